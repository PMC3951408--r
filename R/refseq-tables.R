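#' Published census of annotated-ATG exon position (human RefSeq, Dec 2010)
#'
#' Reference count table from the genome-wide survey of 30035 analyzed
#' human RefSeq transcripts (December 2010 release): the number of
#' transcripts whose annotated start codon falls in exon 1..14. Shipped for
#' worked examples and internal-consistency checks (the counts sum to the
#' analyzed total; exon-1 transcripts are 59.0% of it).
#'
#' @return A tibble `exon`, `n`.
#' @seealso [census_from_counts()] to recompute percentages.
#' @export
refseq_atg_census_2010 <- function() {
  tibble::tibble(
    exon = 1:14,
    n = c(17715L, 8908L, 2369L, 687L, 217L, 77L, 35L, 15L, 6L,
          1L, 1L, 1L, 1L, 2L)
  )
}

#' Published funnel counts of the genome-wide NMD screen (Dec 2010 RefSeq)
#'
#' The stage counts of the original transcriptome-scale screen, shipped so
#' the package's arithmetic (fractions, funnel structure) can be recomputed
#' against them: 35157 records downloaded, 1286 discarded for missing exon
#' structure or joint CDS, 14 discarded with the stop after the last exon,
#' 30035 analyzed; 113 NMD-eliciting under the classic rule, 93 rescuing
#' ORFs in 68 transcripts; on the 5' side 12320 transcripts with the ATG
#' downstream of exon 1, of which 6118 have no uORF, 4130 have an
#' NMD-immune uORF architecture and 2063 an NMD-eliciting one; 335 immune
#' transcripts with a long (>99 nt) non-self-similar uORF, 81 with Kozak
#' context plus protein/domain evidence, 52 final candidates (49 novel).
#'
#' @return A named list of integer counts.
#' @export
refseq_screen_counts_2010 <- function() {
  list(
    downloaded = 35157L,
    discarded_structure_or_joint_cds = 1286L,
    discarded_stop_after_last_exon = 14L,
    analyzed = 30035L,
    classic_eliciting = 113L,
    rescue_orfs = 93L,
    rescue_transcripts = 68L,
    atg_downstream_exon1 = 12320L,
    five_prime_no_uorf = 6118L,
    five_prime_uorf_immune = 4130L,
    five_prime_uorf_eliciting = 2063L,
    long_uorf_no_self_similarity = 335L,
    kozak_with_evidence = 81L,
    final_candidates = 52L,
    novel_candidates = 49L
  )
}
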