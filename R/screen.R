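#' Screen configuration
#'
#' Collects every threshold the screen uses, with the defaults of the
#' genome-wide analysis this package implements: the 55-nt window, the
#' 99-nt functional-uORF length cut-off (strict `>`, so a 100-nt ORF is the
#' smallest functional candidate), the nucleotide-similarity bounds
#' (e-value 1e-6, coverage 0.5), the protein-evidence ratios (0.5 / 0.8)
#' and the expression-verdict alpha (0.05).
#'
#' @param threshold 55-nt window in nt.
#' @param comparator `"gt"` or `"ge"` for the distance test (see
#'   [classify_classic()]).
#' @param min_rescue_orf_length Minimum 3'-UTR rescuing-ORF length in nt.
#' @param min_uorf_length Length bound for functional 5'-UTR candidates.
#' @param uorf_comparator `"gt"` (default) or `"ge"` applied to
#'   `min_uorf_length`.
#' @param max_unit_size Largest rescuing-ORF set enumerated.
#' @param coverage_rule `"junction"` or `"interval"`, see
#'   [find_rescue_units()].
#' @param evalue_max,min_coverage Self-similarity bounds.
#' @param min_positive_ratio,min_align_ratio Protein-evidence bounds.
#' @param alpha Expression-verdict significance level.
#' @return A list of class `nmd_config`.
#' @export
screen_config <- function(threshold = 55L, comparator = "gt",
                          min_rescue_orf_length = 6L,
                          min_uorf_length = 99L, uorf_comparator = "gt",
                          max_unit_size = 3L,
                          coverage_rule = "junction",
                          evalue_max = 1e-6, min_coverage = 0.5,
                          min_positive_ratio = 0.5, min_align_ratio = 0.8,
                          alpha = 0.05) {
  cfg <- list(threshold = as.integer(threshold),
              comparator = match.arg(comparator, c("gt", "ge")),
              min_rescue_orf_length = as.integer(min_rescue_orf_length),
              min_uorf_length = as.integer(min_uorf_length),
              uorf_comparator = match.arg(uorf_comparator, c("gt", "ge")),
              max_unit_size = as.integer(max_unit_size),
              coverage_rule = match.arg(coverage_rule, c("junction", "interval")),
              evalue_max = evalue_max, min_coverage = min_coverage,
              min_positive_ratio = min_positive_ratio,
              min_align_ratio = min_align_ratio, alpha = alpha)
  structure(cfg, class = "nmd_config")
}

#' Read a screen configuration from YAML
#'
#' Unknown keys are rejected; absent keys keep their defaults.
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [screen_config()].
#' @return A list of class `nmd_config`.
#' @export
read_screen_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(screen_config, vals)
}

#' Run the full NMD-immunity / polycistronic-candidate screen
#'
#' Orchestrates the whole analysis over a transcript table: classic 55-nt
#' classification, 3'-UTR rescuing-ORF search, 5'-UTR architecture
#' classification, the functional-uORF length filter, and — where hit and
#' domain tables are supplied — the self-similarity, protein-evidence and
#' domain-sufficiency verdicts, combined per candidate by
#' [candidate_verdict()]. Emits per-transcript verdicts, per-candidate ORF
#' rows and a per-stage funnel report.
#'
#' Candidates come from two branches. The 3' branch: ORFs that are members
#' of a rescuing unit of an NMD-eliciting transcript. The 5' branch: uORFs
#' of transcripts with NMD-immune uORF architecture (`UORF_IMMUNE`) passing
#' the functional-length filter. Evidence tables are optional — without
#' them similarity defaults to `KEEP`, protein evidence to `FALSE` and
#' domain evidence to `NONE`, so no candidate can reach a positive final
#' verdict without supplied evidence.
#'
#' @param tx A transcript table (see [transcripts()]).
#' @param config A [screen_config()].
#' @param gene_ids Optional named character vector mapping transcript id to
#'   gene id (defaults to the transcript id itself), used by the
#'   self-similarity gate.
#' @param nucleotide_hits Optional data frame: `query_id` (transcript id,
#'   ORF start and end joined by `:`), `subject_gene_id`, `evalue`,
#'   `coverage_fraction`.
#' @param protein_hits Optional data frame: `query_id`, `positives`,
#'   `align_length`, `orf_protein_length`.
#' @param domains Optional data frame: `query_id`, `domain_class`,
#'   `identifier`, `span_start`, `span_end`.
#' @return An object of class `nmd_screen`: a list with `transcripts`
#'   (per-transcript verdicts incl. the `architecture` label), `candidates`
#'   (per-ORF rows with all component verdicts), `funnel` (tibble `stage`,
#'   `n`) and `config`. Use [tidy()][generics::tidy] for the candidate
#'   table, [glance()][generics::glance] for the funnel in one row, and
#'   `autoplot()` for a funnel plot.
#' @export
screen_pipeline <- function(tx, config = screen_config(), gene_ids = NULL,
                            nucleotide_hits = NULL, protein_hits = NULL,
                            domains = NULL) {
  if (nrow(tx) == 0) {
    empty <- tibble::tibble(id = character(0))
    return(structure(list(transcripts = empty,
                          candidates = empty_candidates(),
                          funnel = tibble::tibble(stage = character(0),
                                                  n = integer(0)),
                          config = config),
                     class = "nmd_screen"))
  }
  if (is.null(gene_ids)) gene_ids <- stats::setNames(tx$id, tx$id)

  classic <- classify_classic(tx, config$threshold, config$comparator)
  rescue <- find_rescue_units(tx, threshold = config$threshold,
                              min_length = config$min_rescue_orf_length,
                              max_unit_size = config$max_unit_size,
                              comparator = config$comparator,
                              coverage_rule = config$coverage_rule)
  five <- classify_five_prime(tx, config$threshold,
                              comparator = config$comparator)
  arch <- predict_architecture(tx, threshold = config$threshold,
                               comparator = config$comparator,
                               max_unit_size = config$max_unit_size)

  per_tx <- tibble::tibble(
    id = tx$id,
    n_exons = lengths(tx$exon_lengths),
    classic_status = classic$status,
    stop_to_terminal_junction = classic$stop_to_terminal_junction,
    rescued = tx$id %in% rescue$id,
    five_prime_class = five$class
  ) |>
    dplyr::left_join(arch, by = "id")

  # 3' branch candidates: distinct ORFs across rescuing units
  cand3 <- rescue |>
    dplyr::distinct(.data$id, .data$start, .data$end, .data$length,
                    .data$frame, .data$kozak) |>
    dplyr::mutate(branch = "3UTR")

  # 5' branch candidates: uORFs of UORF_IMMUNE transcripts passing the
  # functional-length filter
  immune5 <- tx[tx$id %in% five$id[five$class == "UORF_IMMUNE"], ]
  cand5 <- if (nrow(immune5) > 0) {
    scan_orfs(immune5, region = "5utr",
              min_length = config$min_rescue_orf_length) |>
      dplyr::filter(exceeds(.data$length, config$min_uorf_length,
                            config$uorf_comparator)) |>
      dplyr::select("id", "start", "end", "length", "frame", "kozak") |>
      dplyr::mutate(branch = "5UTR")
  } else {
    empty_candidates()[, c("id", "start", "end", "length", "frame",
                           "kozak", "branch")]
  }

  cands <- dplyr::bind_rows(cand3, cand5)
  if (nrow(cands) > 0) {
    cands$query_id <- paste(cands$id, cands$start, cands$end, sep = ":")
    cands$gene_id <- unname(gene_ids[cands$id])
    cands$similarity <- purrr::map2_chr(cands$query_id, cands$gene_id,
      function(q, g) {
        h <- subset_hits(nucleotide_hits, q)
        self_similarity_verdict(h, g, config$evalue_max, config$min_coverage)
      })
    cands$protein_evidence <- purrr::map_lgl(cands$query_id, function(q) {
      protein_evidence_verdict(subset_hits(protein_hits, q),
                               config$min_positive_ratio,
                               config$min_align_ratio)
    })
    cands$domain_evidence <- purrr::map_chr(cands$query_id, function(q) {
      domain_evidence_verdict(subset_hits(domains, q))
    })
    cands$candidate <- candidate_verdict(cands$similarity, cands$kozak,
                                         cands$protein_evidence,
                                         cands$domain_evidence)
  } else {
    cands <- empty_candidates()
  }

  funnel <- tibble::tribble(
    ~stage, ~n,
    "input", nrow(tx),
    "classic_eliciting", sum(per_tx$classic_status == "ELICITING"),
    "rescued_transcripts", dplyr::n_distinct(rescue$id),
    "rescue_orfs", nrow(cand3),
    "atg_downstream_exon1", sum(per_tx$five_prime_class != "ATG_IN_FIRST_EXON"),
    "five_prime_no_uorf", sum(per_tx$five_prime_class == "NO_UORF"),
    "five_prime_uorf_immune", sum(per_tx$five_prime_class == "UORF_IMMUNE"),
    "five_prime_uorf_eliciting", sum(per_tx$five_prime_class == "UORF_ELICITING"),
    "uorf_candidates_long", sum(cands$branch == "5UTR"),
    "similarity_keep", sum(cands$similarity == "KEEP"),
    "kozak_positive", sum(cands$similarity == "KEEP" & cands$kozak),
    "final_candidates", sum(cands$candidate)
  )
  funnel$n <- as.integer(funnel$n)

  structure(list(transcripts = per_tx, candidates = cands,
                 funnel = funnel, config = config),
            class = "nmd_screen")
}

empty_candidates <- function() {
  tibble::tibble(id = character(0), start = integer(0), end = integer(0),
                 length = integer(0), frame = integer(0), kozak = logical(0),
                 branch = character(0), query_id = character(0),
                 gene_id = character(0), similarity = character(0),
                 protein_evidence = logical(0), domain_evidence = character(0),
                 candidate = logical(0))
}

subset_hits <- function(hits, query) {
  if (is.null(hits)) return(NULL)
  hits[hits$query_id == query, , drop = FALSE]
}

#' @export
print.nmd_screen <- function(x, ...) {
  cat("<nmd_screen> ", nrow(x$transcripts), " transcripts, ",
      nrow(x$candidates), " candidate ORFs\n", sep = "")
  print(x$funnel, n = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Candidate table of a screen
#'
#' @param x An `nmd_screen` object.
#' @param ... Unused.
#' @return The per-candidate tibble with component and combined verdicts.
#' @method tidy nmd_screen
#' @export
tidy.nmd_screen <- function(x, ...) x$candidates

#' One-row funnel summary of a screen
#'
#' @param x An `nmd_screen` object.
#' @param ... Unused.
#' @return A one-row tibble, one column per funnel stage.
#' @method glance nmd_screen
#' @export
glance.nmd_screen <- function(x, ...) {
  tidyr::pivot_wider(x$funnel, names_from = "stage", values_from = "n")
}
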