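#' Self-similarity verdict for a candidate ORF
#'
#' A candidate ORF whose nucleotide sequence aligns strongly to the
#' annotated CDS of its own gene (including alternatively spliced isoforms)
#' is taken to reflect a gene-rearrangement artifact rather than a
#' functional ORF, and is discarded. Hit records come from a pluggable
#' alignment backend as a parsed table; this package never invokes an
#' aligner itself.
#'
#' @param hits A data frame of nucleotide hits for ONE candidate ORF:
#'   columns `subject_gene_id`, `evalue`, `coverage_fraction` (fraction of
#'   the candidate ORF aligned, 0..1). Extra columns are ignored.
#' @param own_gene_id Gene id of the transcript carrying the candidate.
#' @param evalue_max Significance bound: hits with `evalue` above it are
#'   non-significant and never trigger a discard (default 1e-6).
#' @param min_coverage Minimum aligned fraction for a discard (default 0.5).
#' @return `"DISCARD"` iff any same-gene hit has `evalue <= evalue_max` and
#'   `coverage_fraction >= min_coverage`; `"KEEP"` otherwise.
#' @export
self_similarity_verdict <- function(hits, own_gene_id, evalue_max = 1e-6,
                                    min_coverage = 0.5) {
  if (is.null(hits) || nrow(hits) == 0) return("KEEP")
  same <- hits$subject_gene_id == own_gene_id
  strong <- same & hits$evalue <= evalue_max &
    hits$coverage_fraction >= min_coverage
  if (any(strong, na.rm = TRUE)) "DISCARD" else "KEEP"
}

#' Protein-level evidence verdict for a candidate ORF
#'
#' A candidate ORF's translated protein has evidence of being real when any
#' protein-database hit exceeds either of two ratios relative to the ORF
#' protein length: positives ratio (positive-scoring aligned residues /
#' protein length) strictly above `min_positive_ratio`, or alignment-length
#' ratio strictly above `min_align_ratio`.
#'
#' @param hits A data frame of protein hits for ONE candidate: columns
#'   `positives`, `align_length`, `orf_protein_length` (residues).
#' @param min_positive_ratio Default 0.5.
#' @param min_align_ratio Default 0.8.
#' @return `TRUE` iff any hit is significant. Empty hit table returns
#'   `FALSE`; a non-positive `orf_protein_length` is an input error.
#' @export
protein_evidence_verdict <- function(hits, min_positive_ratio = 0.5,
                                     min_align_ratio = 0.8) {
  if (is.null(hits) || nrow(hits) == 0) return(FALSE)
  if (any(hits$orf_protein_length <= 0)) {
    rlang::abort("protein_evidence_verdict: orf_protein_length must be positive")
  }
  any(hits$positives / hits$orf_protein_length > min_positive_ratio |
        hits$align_length / hits$orf_protein_length > min_align_ratio)
}

#' Domain-evidence sufficiency verdict
#'
#' Signal-peptide and transmembrane annotations are unreliable indicators
#' of an independently functional protein (subcellular-localization
#' prediction is error-prone and non-classical secretion exists), so a
#' candidate annotated with ONLY those domain classes is insufficiently
#' supported. Any other domain class suffices.
#'
#' @param domains A data frame of domain annotations for ONE candidate:
#'   column `domain_class` with values `SIGNAL_PEPTIDE`, `TRANSMEMBRANE` or
#'   `OTHER`.
#' @return `"NONE"` (no domains), `"INSUFFICIENT"` (signal peptide and/or
#'   transmembrane only), or `"SUFFICIENT"` (at least one other domain).
#' @export
domain_evidence_verdict <- function(domains) {
  if (is.null(domains) || nrow(domains) == 0) return("NONE")
  bad <- c("SIGNAL_PEPTIDE", "TRANSMEMBRANE")
  if (all(domains$domain_class %in% bad)) "INSUFFICIENT" else "SUFFICIENT"
}

#' Combined functional-candidate verdict
#'
#' A candidate ORF is called a functional (polycistronic) candidate when it
#' is not a self-similarity artifact, has a minimal Kozak context, and is
#' supported by protein-level similarity or by sufficient domain evidence
#' (or both). Vectorized over candidates.
#'
#' @param similarity `"KEEP"`/`"DISCARD"` from [self_similarity_verdict()].
#' @param kozak Logical, from [kozak_positive()].
#' @param protein_evidence Logical, from [protein_evidence_verdict()].
#' @param domain_evidence `"NONE"`/`"INSUFFICIENT"`/`"SUFFICIENT"`, from
#'   [domain_evidence_verdict()].
#' @return Logical vector.
#' @export
candidate_verdict <- function(similarity, kozak, protein_evidence,
                              domain_evidence) {
  similarity == "KEEP" & kozak &
    (protein_evidence | domain_evidence == "SUFFICIENT")
}
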