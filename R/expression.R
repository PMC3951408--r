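#' Welch (unequal-variance) two-sided t-test
#'
#' The heteroscedastic two-tailed t-test used to compare expression with
#' and without NMD inhibition: Welch's statistic with Welch-Satterthwaite
#' degrees of freedom, two-sided p-value. Degenerate inputs are defined
#' rather than errors: when both groups have zero variance the p-value is 1
#' for equal means and 0 for different means.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`.
#' @examples
#' welch_t_test(c(1.1, 1.3, 0.9, 1.0), c(2.2, 2.4, 2.0, 2.6))
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2 || anyNA(a) || anyNA(b) ||
      any(!is.finite(c(a, b)))) {
    rlang::abort("welch_t_test: each group needs >= 2 finite values")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(statistic = if (equal) 0 else Inf,
                          df = NA_real_, p_value = if (equal) 1 else 0,
                          mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_a = mean(a), mean_b = mean(b))
}

#' NMD-sensitivity verdict from a control vs NMD-inhibition comparison
#'
#' GINI (gene identification by NMD inhibition) logic: an NMD substrate
#' accumulates when decay is blocked, so a significant INCREASE under
#' inhibition calls `NMD_SENSITIVE`; a non-significant difference calls
#' `NMD_INSENSITIVE`; a significant DECREASE contradicts NMD stabilization
#' and is `INCONCLUSIVE`. Vectorized.
#'
#' @param p_value Two-sided p-value(s) from [welch_t_test()].
#' @param mean_control,mean_inhibited Group means (on the analysis scale).
#' @param alpha Significance level (default 0.05; per-dataset cut-offs from
#'   the source annotation can be passed instead).
#' @return A tibble: `direction` (`UP_ON_INHIBITION`/`DOWN`/`NONE`) and
#'   `verdict`.
#' @export
gini_verdict <- function(p_value, mean_control, mean_inhibited,
                         alpha = 0.05) {
  direction <- dplyr::case_when(
    mean_inhibited > mean_control ~ "UP_ON_INHIBITION",
    mean_inhibited < mean_control ~ "DOWN",
    TRUE ~ "NONE"
  )
  verdict <- dplyr::case_when(
    p_value >= alpha ~ "NMD_INSENSITIVE",
    direction == "UP_ON_INHIBITION" ~ "NMD_SENSITIVE",
    TRUE ~ "INCONCLUSIVE"
  )
  tibble::tibble(direction = direction, verdict = verdict)
}

#' Per-probe NMD-sensitivity verdicts for an expression table
#'
#' Runs [welch_t_test()] and [gini_verdict()] for every probe of a long
#' expression table against a sample-group assignment. Intensities are
#' log2-transformed before testing by default (the standard analysis scale
#' for microarray intensities); pass `scale = "as_is"` to test the values
#' unchanged. Probes flagged as not uniquely identifying their gene
#' (`unique_gene == FALSE`) are excluded from verdicts but listed with
#' `excluded = TRUE`.
#'
#' @param expr Long tibble: `probe_id`, `sample`, `value`, optionally
#'   `gene_id` and `unique_gene` (logical).
#' @param groups Tibble: `sample`, `group` with values `control` /
#'   `inhibited`.
#' @param alpha Significance level.
#' @param scale `"log2"` (default) or `"as_is"`; recorded in the output.
#' @return A tibble, one row per probe: `probe_id`, `gene_id`,
#'   `n_control`, `n_inhibited`, `mean_control`, `mean_inhibited` (on the
#'   analysis scale), `p_value`, `direction`, `verdict`, `excluded`,
#'   `scale`.
#' @export
gini_verdicts <- function(expr, groups, alpha = 0.05,
                          scale = c("log2", "as_is")) {
  scale <- match.arg(scale)
  if (!all(c("probe_id", "sample", "value") %in% names(expr))) {
    rlang::abort("gini_verdicts: expr needs columns probe_id, sample, value")
  }
  if (!all(groups$group %in% c("control", "inhibited"))) {
    rlang::abort("gini_verdicts: groups$group must be 'control' or 'inhibited'")
  }
  df <- dplyr::left_join(expr, groups, by = "sample")
  if (anyNA(df$group)) {
    rlang::abort("gini_verdicts: some samples have no group assignment")
  }
  if (scale == "log2") df$value <- log2(df$value)
  meta <- df |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      gene_id = if ("gene_id" %in% names(df)) dplyr::first(.data$gene_id) else NA_character_,
      excluded = if ("unique_gene" %in% names(df)) !isTRUE(dplyr::first(.data$unique_gene)) else FALSE,
      .groups = "drop")
  stats_tbl <- df |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(res = list(welch_t_test(
      .data$value[.data$group == "control"],
      .data$value[.data$group == "inhibited"])),
      n_control = sum(.data$group == "control"),
      n_inhibited = sum(.data$group == "inhibited"),
      .groups = "drop") |>
    tidyr::unnest("res")
  out <- dplyr::left_join(meta, stats_tbl, by = "probe_id") |>
    dplyr::rename(mean_control = "mean_a", mean_inhibited = "mean_b")
  v <- gini_verdict(out$p_value, out$mean_control, out$mean_inhibited, alpha)
  out$direction <- v$direction
  out$verdict <- ifelse(out$excluded, NA_character_, v$verdict)
  out$scale <- scale
  dplyr::select(out, "probe_id", "gene_id", "n_control", "n_inhibited",
                "mean_control", "mean_inhibited", "p_value", "direction",
                "verdict", "excluded", "scale")
}

#' Read a probe-by-sample expression matrix with a group sidecar
#'
#' @param path TSV with a `probe_id` column (optionally `gene_id`,
#'   `unique_gene`) and one column per sample.
#' @param groups_path TSV with columns `sample`, `group`
#'   (`control`/`inhibited`).
#' @return A list with `expr` (long tibble) and `groups`.
#' @export
read_expression <- function(path, groups_path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  groups <- readr::read_tsv(groups_path,
                            col_types = readr::cols(
                              sample = readr::col_character(),
                              group = readr::col_character()),
                            progress = FALSE)
  idcols <- intersect(c("probe_id", "gene_id", "unique_gene"), names(wide))
  expr <- tidyr::pivot_longer(wide, cols = -dplyr::all_of(idcols),
                              names_to = "sample", values_to = "value")
  list(expr = expr, groups = groups)
}

#' Match predicted rescuing ORFs against a TIS table
#'
#' Compares predicted translation-initiation positions and ORF sizes with
#' an experimentally mapped TIS table (e.g. from global translation
#' initiation sequencing). A prediction is `matched` when the TIS table
#' contains the same transcript id, the exact start position and the exact
#' ORF length. Per transcript the match type is `EXACT` when every
#' predicted ORF is matched, `PARTIAL` when the transcript has two or more
#' predicted ORFs and exactly one is matched, `NONE` otherwise.
#'
#' @param predictions Tibble: `transcript_id`, `start`, `length` — one row
#'   per predicted rescuing ORF. Duplicate rows are an input error.
#' @param tis_table Tibble with the same three columns, 1-based transcript
#'   coordinates.
#' @return `predictions` with added `matched` (logical, per prediction) and
#'   `match_type` (per transcript, repeated on its rows).
#' @export
match_tis <- function(predictions, tis_table) {
  key <- paste(predictions$transcript_id, predictions$start,
               predictions$length)
  if (anyDuplicated(key)) {
    rlang::abort("match_tis: duplicate prediction keys (transcript_id, start, length)")
  }
  tis_key <- paste(tis_table$transcript_id, tis_table$start, tis_table$length)
  out <- tibble::as_tibble(predictions)
  out$matched <- key %in% tis_key
  out |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(match_type = dplyr::case_when(
      all(.data$matched) ~ "EXACT",
      dplyr::n() >= 2 & sum(.data$matched) == 1 ~ "PARTIAL",
      TRUE ~ "NONE")) |>
    dplyr::ungroup()
}
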