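#' Plot an annotated-ATG exon census
#'
#' @param object An `nmd_census` tibble from [atg_exon_census()] or
#'   [census_from_counts()].
#' @param ... Unused.
#' @return A ggplot: percentage of transcripts per ATG exon ordinal.
#' @method autoplot nmd_census
#' @export
autoplot.nmd_census <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$exon), y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Exon carrying the annotated ATG",
                  y = "% of transcripts",
                  title = "Annotated start-codon exon position") +
    ggplot2::theme_minimal()
}

#' Plot the per-stage funnel of a screen
#'
#' @param object An `nmd_screen` object from [screen_pipeline()].
#' @param ... Unused.
#' @return A ggplot bar chart of transcript/ORF counts per screen stage.
#' @method autoplot nmd_screen
#' @export
autoplot.nmd_screen <- function(object, ...) {
  f <- object$funnel
  f$stage <- factor(f$stage, levels = rev(f$stage))
  ggplot2::ggplot(f, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.2, size = 3) +
    ggplot2::labs(x = "count", y = NULL, title = "NMD screen funnel") +
    ggplot2::theme_minimal()
}

#' Transcript architecture map
#'
#' Draws one transcript in spliced coordinates: exons as alternating
#' blocks, the annotated CDS, exon-exon junction positions, and optionally
#' a set of ORF intervals (e.g. rescuing ORFs or uORFs).
#'
#' @param tx A one-row transcript table.
#' @param orfs Optional tibble with `start`, `end` (e.g. from
#'   [scan_orfs()] or [find_rescue_units()]).
#' @return A ggplot.
#' @export
plot_transcript_map <- function(tx, orfs = NULL) {
  if (nrow(tx) != 1) rlang::abort("plot_transcript_map: one transcript at a time")
  el <- tx$exon_lengths[[1]]
  ends <- cumsum(el)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  exons <- tibble::tibble(xmin = starts - 1, xmax = ends,
                          exon = factor(seq_along(el) %% 2))
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = exons,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = 0, ymax = 0.3, fill = .data$exon),
                       show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("grey80", "grey60")) +
    ggplot2::geom_vline(xintercept = utils::head(ends, -1), linetype = 2,
                        colour = "red3") +
    ggplot2::labs(x = "spliced position (nt)", y = NULL, title = tx$id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.na(tx$cds_start)) {
    p <- p + ggplot2::annotate("rect", xmin = tx$cds_start - 1,
                               xmax = tx$cds_end, ymin = 0.05, ymax = 0.25,
                               fill = "turquoise3", alpha = 0.9)
  }
  if (!is.null(orfs) && nrow(orfs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = orfs,
      ggplot2::aes(xmin = .data$start - 1, xmax = .data$end),
      ymin = 0.35, ymax = 0.5, fill = "purple3", alpha = 0.8)
  }
  p
}
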