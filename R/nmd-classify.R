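exceeds <- function(x, threshold, comparator) {
  if (comparator == "gt") x > threshold else x >= threshold
}

#' Classic 55-nucleotide-rule classification
#'
#' A transcript elicits NMD when the 3'-most nucleotide of its annotated
#' stop codon lies more than `threshold` nucleotides upstream of the
#' terminal exon-exon junction: exon-junction complexes (EJCs) deposited at
#' junctions further downstream are not displaced during the pioneer round
#' of translation. Stops in the terminal exon, within the threshold window,
#' and single-exon transcripts are NMD-immune.
#'
#' @param tx A transcript table with `cds_end` present for every row.
#' @param threshold The window in nt (default 55).
#' @param comparator `"gt"` (default; a stop exactly at the threshold
#'   distance is immune) or `"ge"`.
#' @return A tibble: `id`, `status` (`"ELICITING"`/`"IMMUNE"`), `basis`
#'   (`"CLASSIC_3PRIME"`), `stop_to_terminal_junction` (NA for single-exon
#'   transcripts), and `unneutralized_junctions` (list-column of junction
#'   positions whose EJC survives; empty iff immune).
#' @examples
#' tx <- transcripts("SNURF-like", strrep("A", 300), list(c(200, 100)), 30, 155)
#' classify_classic(tx)
#' @export
classify_classic <- function(tx, threshold = 55L, comparator = c("gt", "ge")) {
  comparator <- match.arg(comparator)
  if (anyNA(tx$cds_end)) {
    rlang::abort(paste0("classify_classic: missing CDS for ",
                        paste(utils::head(tx$id[is.na(tx$cds_end)], 3), collapse = ", ")))
  }
  dist <- stop_junction_distance(tx)
  unneut <- purrr::map2(tx$exon_lengths, tx$cds_end, function(el, ce) {
    pos <- junction_positions(el)
    pos[exceeds(pos - ce, threshold, comparator)]
  })
  tibble::tibble(
    id = tx$id,
    status = ifelse(lengths(unneut) > 0, "ELICITING", "IMMUNE"),
    basis = "CLASSIC_3PRIME",
    stop_to_terminal_junction = dist$distance,
    unneutralized_junctions = unneut
  )
}

#' Does an ORF neutralize the EJC of a junction?
#'
#' Translation of an ORF displaces the EJC at a junction if the ribosome
#' reads across the junction, or terminates inside the immunity window
#' (within `threshold` nt upstream of the junction) having started at or
#' upstream of it: `orf_start <= junction` and
#' `orf_end >= junction - threshold`. ORFs that start downstream of a
#' junction never neutralize it; possible displacement by a ribosome
#' initiating just downstream of a junction is not modeled. Vectorized.
#'
#' @param orf_start,orf_end 1-based inclusive ORF interval(s).
#' @param junction Junction position(s) (last nt of the upstream exon).
#' @param threshold Window in nt (default 55).
#' @return Logical vector.
#' @examples
#' neutralizes(10, 200, 150)   # ORF spans the junction
#' neutralizes(10, 100, 150)   # ends 50 nt upstream: inside the window
#' neutralizes(10, 90, 150)    # ends 60 nt upstream: EJC survives
#' @export
neutralizes <- function(orf_start, orf_end, junction, threshold = 55L) {
  orf_start <= junction & orf_end >= junction - threshold
}

#' Search the 3' UTR for rescuing ORF units
#'
#' For an NMD-eliciting transcript, a rescuing unit is a minimal set of
#' ATG-initiated ORFs in the 3' UTR (no overlap with the annotated CDS)
#' whose translation neutralizes every junction left uncovered by the
#' annotated CDS, i.e. every junction downstream of `cds_end` by more than
#' the threshold. When one ORF suffices the unit has size one; when several
#' ORFs are jointly required they are reported as one unit. All minimal (by
#' set inclusion) units are returned, ordered by total ORF length then by
#' 5'-most start; overlapping ORFs in any frame are all eligible.
#'
#' @param tx A transcript table.
#' @param threshold 55-nt window (default 55).
#' @param min_length Minimum rescuing-ORF length in nt (default 6; the
#'   screen imposes no lower bound on 3'-UTR rescuers beyond start + stop).
#' @param max_unit_size Largest ORF set enumerated per transcript
#'   (default 3).
#' @param comparator Threshold comparator, as in [classify_classic()].
#' @param coverage_rule `"junction"` (default): each required junction must
#'   be neutralized by some member. `"interval"`: in addition, members must
#'   chain into a continuous block — each ORF after the first must start
#'   while the preceding coverage is still within the threshold window.
#' @return A tibble with one row per ORF per unit: `id`, `unit` (ordinal
#'   within transcript), `unit_size`, `start`, `end`, `length`, `frame`,
#'   `kozak`, plus a list-column `neutralized` (junctions that member
#'   covers). Transcripts that are already immune, or have no rescuing
#'   unit, contribute no rows.
#' @export
find_rescue_units <- function(tx, threshold = 55L, min_length = 6L,
                              max_unit_size = 3L,
                              comparator = c("gt", "ge"),
                              coverage_rule = c("junction", "interval")) {
  comparator <- match.arg(comparator)
  coverage_rule <- match.arg(coverage_rule)
  verdicts <- classify_classic(tx, threshold, comparator)
  out <- list()
  for (i in seq_len(nrow(tx))) {
    if (verdicts$status[i] != "ELICITING") next
    required <- verdicts$unneutralized_junctions[[i]]
    orfs <- scan_orfs(tx[i, ], region = "3utr", min_length = min_length)
    if (nrow(orfs) == 0) next
    covers <- purrr::map2(orfs$start, orfs$end, function(s, e) {
      required[neutralizes(s, e, required, threshold)]
    })
    useful <- which(lengths(covers) > 0)
    if (length(useful) == 0) next
    units <- minimal_covers(covers[useful], required,
                            starts = orfs$start[useful],
                            ends = orfs$end[useful],
                            max_size = max_unit_size,
                            threshold = threshold,
                            interval = coverage_rule == "interval")
    if (length(units) == 0) next
    lens <- orfs$length[useful]
    ord <- order(purrr::map_int(units, ~ sum(lens[.x])),
                 purrr::map_int(units, ~ min(orfs$start[useful][.x])))
    units <- units[ord]
    rows <- purrr::imap_dfr(units, function(members, u) {
      j <- useful[members]
      tibble::tibble(
        id = tx$id[i], unit = u, unit_size = length(j),
        start = orfs$start[j], end = orfs$end[j],
        length = orfs$length[j], frame = orfs$frame[j],
        kozak = orfs$kozak[j],
        neutralized = covers[useful][members]
      )
    })
    out[[length(out) + 1L]] <- rows
  }
  if (length(out) == 0) {
    return(tibble::tibble(id = character(0), unit = integer(0),
                          unit_size = integer(0), start = integer(0),
                          end = integer(0), length = integer(0),
                          frame = integer(0), kozak = logical(0),
                          neutralized = list()))
  }
  dplyr::bind_rows(out)
}

# All minimal (by set inclusion) subsets of ORFs whose covered junctions
# union to `required`, enumerated up to `max_size` members.
minimal_covers <- function(covers, required, starts, ends, max_size,
                           threshold, interval = FALSE) {
  n <- length(covers)
  found <- list()
  for (k in seq_len(min(max_size, n))) {
    for (subset in utils::combn(n, k, simplify = FALSE)) {
      # skip supersets of an already-found (smaller) cover
      if (any(purrr::map_lgl(found, ~ all(.x %in% subset)))) next
      covered <- sort(unique(unlist(covers[subset])))
      if (!all(required %in% covered)) next
      if (interval && k > 1L) {
        ord <- subset[order(starts[subset])]
        gaps_ok <- all(starts[ord][-1] <= ends[ord][-length(ord)] + threshold + 1L)
        if (!gaps_ok) next
      }
      found[[length(found) + 1L]] <- subset
    }
  }
  found
}

#' 5'-UTR architecture classification under the extended 55-nt rule
#'
#' Extends the NMD-eliciting question to the 5' UTR. The scanning 43S
#' pre-initiation complex is assumed to displace every EJC it traverses on
#' the way to the first ATG it encounters, so only junctions between the
#' end of the first upstream ORF (uORF) and the annotated ATG matter.
#' Classes:
#' \describe{
#'   \item{ATG_IN_FIRST_EXON}{annotated ATG in exon 1 — no upstream EJC can
#'     remain, and re-initiation potential cannot be assessed from sequence.}
#'   \item{NO_UORF}{no ATG-initiated uORF upstream of the annotated ATG:
#'     scanning removes all upstream EJCs.}
#'   \item{UORF_IMMUNE}{uORF(s) present and every junction strictly between
#'     the first uORF's end and the annotated ATG is neutralized by some
#'     uORF under the 55-nt window.}
#'   \item{UORF_ELICITING}{uORF(s) present but at least one such junction
#'     retains its EJC.}
#' }
#' uORFs must terminate upstream of the annotated ATG (no overlap with the
#' annotated CDS, mirroring the 3'-UTR rule).
#'
#' @param tx A transcript table with `cds_start` present for every row.
#' @param threshold 55-nt window (default 55).
#' @param min_length Minimum uORF length in nt used for classification
#'   (default 6: any translatable uORF displaces EJCs regardless of size).
#' @param comparator Threshold comparator, as in [classify_classic()].
#' @return A tibble: `id`, `class`, `n_uorfs`, `first_uorf_end` (NA when no
#'   uORF), `unneutralized_junctions` (list-column; non-empty only for
#'   UORF_ELICITING).
#' @export
classify_five_prime <- function(tx, threshold = 55L, min_length = 6L,
                                comparator = c("gt", "ge")) {
  comparator <- match.arg(comparator)
  if (anyNA(tx$cds_start)) {
    rlang::abort(paste0("classify_five_prime: missing CDS for ",
                        paste(utils::head(tx$id[is.na(tx$cds_start)], 3), collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(tx)), function(i) {
    cs <- tx$cds_start[i]
    jpos <- junction_positions(tx$exon_lengths[[i]])
    res <- tibble::tibble(id = tx$id[i], class = NA_character_,
                          n_uorfs = 0L, first_uorf_end = NA_integer_,
                          unneutralized_junctions = list(integer(0)))
    if (length(jpos) == 0 || cs <= jpos[1]) {
      res$class <- "ATG_IN_FIRST_EXON"
      return(res)
    }
    uorfs <- if (cs >= 7L) {
      scan_orfs(tx[i, ], region = "5utr", min_length = min_length)
    } else {
      tibble::tibble(start = integer(0), end = integer(0))
    }
    if (nrow(uorfs) == 0) {
      res$class <- "NO_UORF"
      return(res)
    }
    res$n_uorfs <- nrow(uorfs)
    first_end <- uorfs$end[which.min(uorfs$start)]
    res$first_uorf_end <- first_end
    between <- jpos[jpos > first_end & jpos < cs]
    surviving <- between[!purrr::map_lgl(between, function(j) {
      any(neutralizes(uorfs$start, uorfs$end, j, threshold))
    })]
    res$unneutralized_junctions <- list(surviving)
    res$class <- if (length(surviving) == 0) "UORF_IMMUNE" else "UORF_ELICITING"
    res
  })
}

#' Census of the exon carrying the annotated ATG
#'
#' Locates the exon ordinal containing `cds_start` for each transcript (by
#' prefix-sum bisection of the exon partition) and tabulates counts and
#' percentages per exon.
#'
#' @param tx A transcript table with `cds_start` present for every row.
#' @return A tibble of class `nmd_census`: `exon`, `n`, `pct`
#'   (`n / total * 100`, unrounded).
#' @seealso [census_from_counts()] to recompute percentages from an
#'   existing count table such as [refseq_atg_census_2010()].
#' @export
atg_exon_census <- function(tx) {
  if (anyNA(tx$cds_start)) {
    rlang::abort("atg_exon_census: every transcript must carry cds_start")
  }
  exon <- purrr::map2_int(tx$exon_lengths, tx$cds_start, function(el, cs) {
    findInterval(cs - 1L, cumsum(el)) + 1L
  })
  census_from_counts(dplyr::count(tibble::tibble(exon = exon), .data$exon))
}

#' Percentages for an exon-position count table
#'
#' @param counts A data frame with columns `exon` and `n`.
#' @param total Denominator for percentages (default `sum(counts$n)`).
#' @return A tibble of class `nmd_census`: `exon`, `n`, `pct`.
#' @export
census_from_counts <- function(counts, total = sum(counts$n)) {
  out <- tibble::tibble(exon = as.integer(counts$exon),
                        n = as.integer(counts$n)) |>
    dplyr::arrange(.data$exon) |>
    dplyr::mutate(pct = .data$n / total * 100)
  class(out) <- c("nmd_census", class(out))
  out
}

#' Predict the architecture label of each transcript
#'
#' Combines the classic classification, the 3'-UTR rescue search and the
#' 5'-UTR classification into a single architecture label per transcript —
#' the label vocabulary the synthetic generator plants and the screen
#' recovers:
#' `MONO_IMMUNE` (single exon), `CLASSIC_PTC` (eliciting, no rescuing
#' unit), `BICISTRONIC_3PRIME` (eliciting, rescued by a single-ORF unit),
#' `MULTI_ORF_RESCUE` (eliciting, rescued only by multi-ORF units),
#' `STOP_NEAR_JUNCTION` (immune with the stop 1..threshold nt upstream of
#' the terminal junction), and for stops in the terminal exon the 5'-UTR
#' class (`ATG_EXON1`, `NO_UORF`, `UORF_IMMUNE`, `UORF_ELICITING`).
#'
#' @inheritParams find_rescue_units
#' @return A tibble `id`, `architecture`.
#' @export
predict_architecture <- function(tx, threshold = 55L,
                                 comparator = c("gt", "ge"),
                                 max_unit_size = 3L) {
  comparator <- match.arg(comparator)
  classic <- classify_classic(tx, threshold, comparator)
  rescue <- find_rescue_units(tx, threshold = threshold,
                              max_unit_size = max_unit_size,
                              comparator = comparator)
  five <- classify_five_prime(tx, threshold, comparator = comparator)
  purrr::map_chr(seq_len(nrow(tx)), function(i) {
    id <- tx$id[i]
    if (length(tx$exon_lengths[[i]]) == 1L) return("MONO_IMMUNE")
    if (classic$status[i] == "ELICITING") {
      units <- rescue[rescue$id == id, ]
      if (nrow(units) == 0) return("CLASSIC_PTC")
      if (any(units$unit_size == 1L)) return("BICISTRONIC_3PRIME")
      return("MULTI_ORF_RESCUE")
    }
    d <- classic$stop_to_terminal_junction[i]
    if (!is.na(d) && d > 0) return("STOP_NEAR_JUNCTION")
    cls <- five$class[five$id == id]
    c(ATG_IN_FIRST_EXON = "ATG_EXON1", NO_UORF = "NO_UORF",
      UORF_IMMUNE = "UORF_IMMUNE", UORF_ELICITING = "UORF_ELICITING")[[cls]]
  }) |>
    (\(lab) tibble::tibble(id = tx$id, architecture = lab))()
}
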