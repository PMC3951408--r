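TSV_COLUMNS <- c("id", "sequence", "exon_lengths", "cds_start", "cds_end")

#' Read transcript models from a file
#'
#' Two formats are supported. `"tsv"` is the package's own dialect: a
#' tab-separated file with header
#' `id  sequence  exon_lengths  cds_start  cds_end`, where `exon_lengths`
#' is comma-separated and `cds_start`/`cds_end` may be empty (CDS absent).
#' `"genbank"` reads RefSeq-style GenBank flat-file records, taking the
#' exon partition from the record's `exon` features (in transcript order)
#' and the CDS from the `CDS` feature.
#'
#' Records are filtered on read, mirroring the record-validity rules of the
#' genome-wide screen: records without exon features (or with an empty
#' `exon_lengths` field) are discarded as missing structure; records whose
#' CDS is a compound `join(...)` location are discarded as joint-CDS;
#' records whose annotated stop coordinate lies after the last exon are
#' discarded. The tally is attached as the filter report, retrievable with
#' [filter_report()].
#'
#' @param path File to read.
#' @param format `"tsv"` or `"genbank"`.
#' @return A transcript table (validated) with attribute `filter_report`.
#' @export
read_transcripts <- function(path, format = c("tsv", "genbank")) {
  format <- match.arg(format)
  raw <- switch(format,
                tsv = read_transcripts_tsv(path),
                genbank = read_transcripts_genbank(path))
  n_total <- nrow(raw)
  missing_structure <- purrr::map_lgl(raw$exon_lengths, ~ length(.x) == 0)
  joint <- !missing_structure & raw$joint_cds
  seqlen <- nchar(raw$sequence)
  stop_after <- !missing_structure & !joint &
    !is.na(raw$cds_end) & raw$cds_end > seqlen
  keep <- !missing_structure & !joint & !stop_after
  report <- tibble::tibble(
    total_read = n_total,
    discarded_missing_structure = sum(missing_structure),
    discarded_joint_cds = sum(joint),
    discarded_stop_after_last_exon = sum(stop_after),
    retained = sum(keep)
  )
  kept <- raw[keep, ]
  tx <- transcripts(kept$id, kept$sequence, kept$exon_lengths,
                    kept$cds_start, kept$cds_end)
  attr(tx, "filter_report") <- report
  tx
}

#' @rdname read_transcripts
#' @param x A transcript table returned by [read_transcripts()].
#' @return For `filter_report()`: a one-row tibble with columns
#'   `total_read`, `discarded_missing_structure`, `discarded_joint_cds`,
#'   `discarded_stop_after_last_exon`, `retained`.
#' @export
filter_report <- function(x) attr(x, "filter_report")

read_transcripts_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(TSV_COLUMNS, header)
  if (length(missing) > 0) {
    rlang::abort(paste0(path, ": malformed transcript TSV, missing column(s) ",
                        paste(missing, collapse = ", ")))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), sequence = readr::col_character(),
    exon_lengths = readr::col_character(),
    cds_start = readr::col_integer(), cds_end = readr::col_integer()
  ), progress = FALSE)
  tibble::tibble(
    id = df$id,
    sequence = toupper(df$sequence),
    exon_lengths = purrr::map(df$exon_lengths, function(s) {
      if (is.na(s) || !nzchar(trimws(s))) integer(0) else parse_exon_lengths(s)
    }),
    cds_start = df$cds_start,
    cds_end = df$cds_end,
    joint_cds = FALSE
  )
}

# Minimal parser for RefSeq-style GenBank flat files: LOCUS, VERSION/
# ACCESSION, FEATURES (exon and CDS features with transcript-space
# positions), ORIGIN sequence. Multi-record files are split on "//".
read_transcripts_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^LOCUS", lines[1])) {
    rlang::abort(paste0(path, ": not a GenBank flat file (no LOCUS line)"))
  }
  rec_start <- grep("^LOCUS", lines)
  rec_end <- grep("^//\\s*$", lines)
  if (length(rec_end) < length(rec_start)) {
    rlang::abort(paste0(path, ": record starting at line ",
                        rec_start[length(rec_end) + 1],
                        " is not terminated by //"))
  }
  purrr::map2_dfr(rec_start, rec_end[seq_along(rec_start)], function(a, b) {
    parse_genbank_record(lines[a:b], first_line = a, path = path)
  })
}

parse_genbank_record <- function(rl, first_line, path) {
  id <- sub("^LOCUS\\s+(\\S+).*", "\\1", rl[1])
  ver <- grep("^VERSION", rl, value = TRUE)
  if (length(ver) > 0) id <- sub("^VERSION\\s+(\\S+).*", "\\1", ver[1])
  ori <- grep("^ORIGIN", rl)
  if (length(ori) == 0) {
    rlang::abort(paste0(path, ": record at line ", first_line, " has no ORIGIN"))
  }
  seq_lines <- rl[(ori[1] + 1L):(length(rl) - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feat_keys <- grep("^ {5}\\S", rl)
  exon_lengths <- integer(0)
  cds_start <- NA_integer_; cds_end <- NA_integer_
  joint_cds <- FALSE
  exon_iv <- list()
  for (k in feat_keys) {
    key <- sub("^ {5}(\\S+)\\s+.*", "\\1", rl[k])
    loc <- sub("^ {5}\\S+\\s+", "", rl[k])
    if (key == "exon") {
      m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
      if (length(m) == 3) {
        exon_iv[[length(exon_iv) + 1L]] <- as.integer(m[2:3])
      }
    } else if (key == "CDS" && is.na(cds_start) && !joint_cds) {
      if (grepl("join\\(", loc)) {
        joint_cds <- TRUE
      } else {
        m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
        if (length(m) == 3) {
          cds_start <- as.integer(m[2]); cds_end <- as.integer(m[3])
        }
      }
    }
  }
  if (length(exon_iv) > 0) {
    exon_iv <- exon_iv[order(purrr::map_int(exon_iv, 1))]
    starts <- purrr::map_int(exon_iv, 1); ends <- purrr::map_int(exon_iv, 2)
    contiguous <- starts[1] == 1L &&
      all(starts[-1] == utils::head(ends, -1) + 1L)
    exon_lengths <- if (contiguous) ends - starts + 1L else integer(0)
  }
  tibble::tibble(id = id, sequence = sequence,
                 exon_lengths = list(exon_lengths),
                 cds_start = cds_start, cds_end = cds_end,
                 joint_cds = joint_cds)
}

#' Write a transcript table in the package TSV dialect
#'
#' Inverse of [read_transcripts()] for `format = "tsv"`: read -> write ->
#' read is the identity on retained records.
#'
#' @param tx A transcript table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(tx, path) {
  out <- tibble::tibble(
    id = tx$id, sequence = tx$sequence,
    exon_lengths = purrr::map_chr(tx$exon_lengths, paste, collapse = ","),
    cds_start = tx$cds_start, cds_end = tx$cds_end
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write candidate ORFs as TSV (and optionally BED6)
#'
#' The TSV has a stable, documented column order:
#' `id, start, end, length, frame, kozak, branch, similarity,
#' protein_evidence, domain_evidence, candidate` (verdict columns are
#' filled with NA when absent from `rows`). The optional BED6 export gives
#' each ORF interval in transcript space with the standard 0-based
#' half-open shift: the 1-based inclusive interval `74..184` becomes BED
#' `73  184`.
#'
#' @param rows A data frame with at least `id`, `start`, `end`.
#' @param path Output TSV path.
#' @param bed_path Optional BED6 output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(rows, path, bed_path = NULL) {
  cols <- c("id", "start", "end", "length", "frame", "kozak", "branch",
            "similarity", "protein_evidence", "domain_evidence", "candidate")
  out <- tibble::as_tibble(rows)
  for (cl in setdiff(cols, names(out))) out[[cl]] <- NA
  out <- out[, cols]
  readr::write_tsv(out, path, na = "", progress = FALSE)
  if (!is.null(bed_path)) {
    bed <- tibble::tibble(
      chrom = out$id,
      chromStart = as.integer(out$start) - 1L,
      chromEnd = as.integer(out$end),
      name = paste0(out$id, ":", out$start, "-", out$end),
      score = 0L, strand = "+"
    )
    readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_candidates
#' @return For `read_candidates()`: the candidate tibble.
#' @export
read_candidates <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), length = readr::col_integer(),
    frame = readr::col_integer(), kozak = readr::col_logical(),
    branch = readr::col_character(), similarity = readr::col_character(),
    protein_evidence = readr::col_logical(),
    domain_evidence = readr::col_character(),
    candidate = readr::col_logical()
  ), progress = FALSE)
}
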