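#' Build a transcript table
#'
#' The unit of every classification in nmdscreen is a spliced transcript
#' model: the mature (intron-free) mRNA sequence 5'->3', the ordered exon
#' partition of that sequence, and the annotated CDS given as 1-based
#' inclusive spliced coordinates. `transcripts()` assembles a tibble with one
#' row per transcript; `as_transcripts()` coerces and validates an existing
#' data frame.
#'
#' All coordinates throughout the package are 1-based inclusive on the
#' spliced mRNA; genomic coordinates are never used. `cds_start` is the
#' position of the A of the annotated ATG; `cds_end` is the 3'-most
#' nucleotide of the annotated stop codon, so the CDS interval includes the
#' stop codon and `cds_end - cds_start + 1` is divisible by 3.
#'
#' @param id Character vector of transcript accessions.
#' @param sequence Character vector of spliced mRNA sequences over
#'   `A,C,G,T,N` (case-insensitive; stored upper-case).
#' @param exon_lengths List of integer vectors: ordered exon lengths in nt.
#'   A plain comma-separated string per transcript is also accepted.
#' @param cds_start,cds_end Integer vectors (NA when the CDS is absent).
#' @return A tibble with columns `id`, `sequence`, `exon_lengths`
#'   (list-column), `cds_start`, `cds_end`.
#' @examples
#' tx <- transcripts("T1", "ATGAAATAGGCCGCC", list(c(9, 6)), 1, 9)
#' junctions(tx)
#' @export
transcripts <- function(id, sequence, exon_lengths, cds_start = NA_integer_,
                        cds_end = NA_integer_) {
  if (is.character(exon_lengths)) exon_lengths <- as.list(exon_lengths)
  exon_lengths <- purrr::map(exon_lengths, parse_exon_lengths)
  out <- tibble::tibble(
    id = as.character(id),
    sequence = toupper(as.character(sequence)),
    exon_lengths = exon_lengths,
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end)
  )
  validate_transcripts(out)
}

parse_exon_lengths <- function(x) {
  if (is.character(x)) x <- strsplit(x, ",", fixed = TRUE)[[1]]
  as.integer(trimws(x))
}

#' @rdname transcripts
#' @param x A data frame with the columns of a transcript table.
#' @param require_atg If `TRUE`, additionally require that the sequence at
#'   `cds_start` is literally `ATG` (a "validated" record).
#' @export
as_transcripts <- function(x, require_atg = FALSE) {
  need <- c("id", "sequence", "exon_lengths")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    rlang::abort(paste0("transcript table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!"cds_start" %in% names(x)) x$cds_start <- NA_integer_
  if (!"cds_end" %in% names(x)) x$cds_end <- NA_integer_
  transcripts(x$id, x$sequence, x$exon_lengths, x$cds_start, x$cds_end) |>
    validate_transcripts(require_atg = require_atg)
}

#' Validate transcript-table invariants
#'
#' Checks, row by row: exon lengths are positive and sum to the sequence
#' length; the sequence alphabet is `A,C,G,T,N`; when a CDS is annotated,
#' `1 <= cds_start < cds_end <= length`, the CDS length is divisible by 3,
#' and (optionally) the CDS starts with ATG. Aborts with the offending
#' transcript id on the first violation.
#'
#' @inheritParams as_transcripts
#' @return `x`, invisibly usable in a pipe (returned visibly).
#' @export
validate_transcripts <- function(x, require_atg = FALSE) {
  for (i in seq_len(nrow(x))) {
    id <- x$id[i]
    el <- x$exon_lengths[[i]]
    seq_len_i <- nchar(x$sequence[i])
    if (length(el) == 0 || anyNA(el) || any(el <= 0)) {
      rlang::abort(paste0(id, ": exon_lengths must be a non-empty vector of positive integers"))
    }
    if (sum(el) != seq_len_i) {
      rlang::abort(paste0(id, ": exon lengths sum to ", sum(el),
                          " but sequence has ", seq_len_i, " nt"))
    }
    if (grepl("[^ACGTN]", x$sequence[i])) {
      rlang::abort(paste0(id, ": sequence contains characters outside A,C,G,T,N"))
    }
    cs <- x$cds_start[i]; ce <- x$cds_end[i]
    if (xor(is.na(cs), is.na(ce))) {
      rlang::abort(paste0(id, ": cds_start and cds_end must both be present or both absent"))
    }
    if (!is.na(cs)) {
      if (cs < 1 || ce <= cs || ce > seq_len_i) {
        rlang::abort(paste0(id, ": CDS coordinates violate 1 <= cds_start < cds_end <= length"))
      }
      if ((ce - cs + 1L) %% 3L != 0L) {
        rlang::abort(paste0(id, ": CDS length ", ce - cs + 1L, " is not divisible by 3"))
      }
      if (require_atg && substr(x$sequence[i], cs, cs + 2L) != "ATG") {
        rlang::abort(paste0(id, ": annotated CDS does not start with ATG"))
      }
    }
  }
  x
}

#' Exon-exon junction positions of an exon partition
#'
#' A junction is recorded as the 1-based spliced coordinate of the LAST
#' nucleotide of a non-terminal exon: junction k lies between `positions[k]`
#' and `positions[k] + 1`. A single-exon transcript has no junctions.
#'
#' @param exon_lengths Integer vector of ordered exon lengths.
#' @return Integer vector of junction positions (prefix sums excluding the
#'   final exon), strictly increasing, possibly empty.
#' @examples
#' junction_positions(c(100, 50, 80))
#' @export
junction_positions <- function(exon_lengths) {
  exon_lengths <- as.integer(exon_lengths)
  if (length(exon_lengths) == 0) {
    rlang::abort("exon_lengths must be non-empty")
  }
  n <- length(exon_lengths)
  if (n == 1L) return(integer(0))
  cumsum(exon_lengths)[-n]
}

#' Junction table for a transcript set
#'
#' @param tx A transcript table (see [transcripts()]).
#' @return A tibble with one row per junction: `id`, `junction` (ordinal),
#'   `position` (last nucleotide of the upstream exon). Single-exon
#'   transcripts contribute no rows.
#' @export
junctions <- function(tx) {
  purrr::map2_dfr(tx$id, tx$exon_lengths, function(id, el) {
    pos <- junction_positions(el)
    tibble::tibble(id = id,
                   junction = seq_along(pos),
                   position = pos)
  })
}

#' Length of a coordinate interval under the 1-based inclusive convention
#'
#' ORF intervals in this package include the stop codon, so an ORF spanning
#' 74..184 has length 111 nt. Vectorized over `start` and `end`.
#'
#' @param start,end 1-based inclusive spliced coordinates, `start <= end`.
#' @return `end - start + 1` as an integer vector.
#' @examples
#' orf_length(74, 184)
#' @export
orf_length <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end, na.rm = TRUE)) {
    rlang::abort("orf_length: start must not exceed end")
  }
  end - start + 1L
}

#' Distance from the annotated stop codon to the terminal junction
#'
#' The quantity on which the 55-nucleotide rule operates: the terminal
#' exon-exon junction position minus `cds_end` (the 3'-most nucleotide of
#' the stop codon). Negative values mean the stop lies in the terminal exon;
#' single-exon transcripts have no junction and yield `NA` (callers treat
#' that as NMD-immune).
#'
#' @param tx A transcript table with `cds_end` present for every row.
#' @return A tibble `id`, `terminal_junction`, `distance` (both `NA` for
#'   single-exon transcripts).
#' @examples
#' tx <- transcripts("SNURF-like", strrep("A", 300), list(c(200, 100)), 30, 155)
#' stop_junction_distance(tx)
#' @export
stop_junction_distance <- function(tx) {
  if (anyNA(tx$cds_end)) {
    bad <- tx$id[is.na(tx$cds_end)]
    rlang::abort(paste0("stop_junction_distance: missing cds_end for ",
                        paste(utils::head(bad, 3), collapse = ", ")))
  }
  term <- purrr::map_int(tx$exon_lengths, function(el) {
    pos <- junction_positions(el)
    if (length(pos) == 0) NA_integer_ else pos[length(pos)]
  })
  tibble::tibble(id = tx$id,
                 terminal_junction = term,
                 distance = term - tx$cds_end)
}
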