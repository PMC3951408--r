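STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Enumerate ATG-initiated ORFs in a region of a spliced transcript
#'
#' Scans the three reading frames 5'->3' within a region and reports every
#' open reading frame that (i) starts with ATG, (ii) ends with the first
#' in-frame stop codon downstream of that ATG, (iii) lies entirely inside
#' the region, and (iv) has length (stop codon included) of at least
#' `min_length`. Overlapping and nested ORFs, in the same or different
#' frames, are all reported. ORFs whose first in-frame stop falls outside
#' the region are not reported. Codons containing `N` are treated as neither
#' ATG nor stop, so they can neither open nor close an ORF.
#'
#' `scan_orfs()` operates on a transcript table and understands the three
#' named regions the NMD screen uses; `scan_orfs_seq()` is the low-level
#' single-sequence worker.
#'
#' @param tx A transcript table (see [transcripts()]).
#' @param region `"full"` (whole transcript), `"5utr"`
#'   (`1 .. cds_start - 1`), or `"3utr"` (`cds_end + 1 .. length`). The UTR
#'   regions require the corresponding CDS coordinate; restricting the scan
#'   to a UTR is also what enforces the no-overlap rule between candidate
#'   ORFs and the annotated CDS.
#' @param min_length Minimum ORF length in nt, stop codon included
#'   (default 6 = start plus stop codon).
#' @return A tibble: `id`, `start`, `end`, `length`, `frame` (0/1/2 =
#'   `(start - 1) %% 3`), `kozak` (minimal Kozak context, see
#'   [kozak_positive()]), `region`.
#' @examples
#' tx <- transcripts("T1", "ATGATGTAAGCC", list(12))
#' scan_orfs(tx, region = "full")
#' @export
scan_orfs <- function(tx, region = c("full", "5utr", "3utr"), min_length = 6L) {
  region <- match.arg(region)
  purrr::pmap_dfr(
    list(tx$id, tx$sequence, tx$cds_start, tx$cds_end),
    function(id, seq, cs, ce) {
      n <- nchar(seq)
      bounds <- switch(region,
        full = c(1L, n),
        "5utr" = {
          if (is.na(cs)) rlang::abort(paste0(id, ": 5utr scan needs cds_start"))
          c(1L, cs - 1L)
        },
        "3utr" = {
          if (is.na(ce)) rlang::abort(paste0(id, ": 3utr scan needs cds_end"))
          c(ce + 1L, n)
        }
      )
      if (bounds[2] < bounds[1]) {
        return(tibble::tibble(id = character(0), start = integer(0),
                              end = integer(0), length = integer(0),
                              frame = integer(0), kozak = logical(0),
                              region = character(0)))
      }
      orfs <- scan_orfs_seq(seq, from = bounds[1], to = bounds[2],
                            min_length = min_length)
      orfs$id <- id
      orfs$kozak <- kozak_positive(seq, orfs$start)
      orfs$region <- region
      orfs[, c("id", "start", "end", "length", "frame", "kozak", "region")]
    }
  )
}

#' @rdname scan_orfs
#' @param sequence A single nucleotide string.
#' @param from,to 1-based inclusive region bounds within the sequence.
#' @export
scan_orfs_seq <- function(sequence, from = 1L, to = nchar(sequence),
                          min_length = 6L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  from <- as.integer(from); to <- as.integer(to)
  if (from < 1L || to > n || from > to) {
    rlang::abort("scan_orfs_seq: region outside transcript bounds")
  }
  out <- list()
  for (offset in 0:2) {
    first <- from + offset
    if (first + 2L > to) next
    codon_starts <- seq.int(first, to - 2L, by = 3L)
    codons <- substring(sequence, codon_starts, codon_starts + 2L)
    atg_idx <- which(codons == "ATG")
    stop_idx <- which(codons %in% STOP_CODONS)
    if (length(atg_idx) == 0 || length(stop_idx) == 0) next
    # first stop codon strictly downstream of each ATG, in the same frame
    nxt <- stop_idx[findInterval(atg_idx, stop_idx) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    s <- codon_starts[atg_idx[ok]]
    e <- codon_starts[nxt[ok]] + 2L
    len <- e - s + 1L
    keep <- len >= min_length
    if (!any(keep)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      start = s[keep], end = e[keep], length = len[keep],
      frame = (s[keep] - 1L) %% 3L
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          length = integer(0), frame = integer(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$end)
}

#' Minimal Kozak context of an ATG
#'
#' The minimal positive Kozak context used by the screen: a purine (A or G)
#' at position -3 relative to the A of the ATG. Positions -3 that do not
#' exist (ATG within the first three nucleotides) are truncated contexts and
#' score negative.
#'
#' @param sequence A nucleotide string (a single transcript sequence).
#' @param atg_start 1-based position(s) of the A of an ATG; vectorized.
#' @return Logical vector: `TRUE` iff the -3 base exists and is A or G.
#' @examples
#' kozak_positive("CTTACTATGT", 7) # -3 base is A
#' @export
kozak_positive <- function(sequence, atg_start) {
  sequence <- toupper(sequence)
  atg_start <- as.integer(atg_start)
  minus3 <- ifelse(atg_start >= 4L,
                   substring(sequence, atg_start - 3L, atg_start - 3L),
                   NA_character_)
  !is.na(minus3) & minus3 %in% c("A", "G")
}

#' Translate an ORF interval to protein
#'
#' Standard-code translation of the codons from `start` to `end - 3`; the
#' terminal stop codon is not included, so the protein has
#' `(end - start + 1) / 3 - 1` residues. An in-frame stop strictly inside
#' the interval violates the ORF invariant and is an error.
#'
#' @param sequence A nucleotide string.
#' @param start,end 1-based inclusive ORF interval, stop codon included;
#'   length divisible by 3 and at least 6.
#' @return The amino-acid string.
#' @examples
#' translate_orf("ATGGCTTAA", 1, 9)
#' @export
translate_orf <- function(sequence, start, end) {
  sequence <- toupper(sequence)
  start <- as.integer(start); end <- as.integer(end)
  len <- end - start + 1L
  if (len < 6L || len %% 3L != 0L) {
    rlang::abort("translate_orf: interval length must be >= 6 and divisible by 3")
  }
  aa <- seqinr::translate(seqinr::s2c(substr(sequence, start, end - 3L)))
  if (any(aa == "*")) {
    rlang::abort("translate_orf: in-frame stop codon inside the ORF body")
  }
  paste(aa, collapse = "")
}
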