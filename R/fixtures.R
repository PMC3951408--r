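ARCHITECTURE_LABELS <- c("MONO_IMMUNE", "CLASSIC_PTC", "BICISTRONIC_3PRIME",
                         "STOP_NEAR_JUNCTION", "ATG_EXON1", "NO_UORF",
                         "UORF_IMMUNE", "UORF_ELICITING", "MULTI_ORF_RESCUE")

r_int <- function(a, b) {
  if (b < a) rlang::abort("fixture generation: infeasible coordinate range")
  if (a == b) return(as.integer(a))
  sample(seq.int(a, b), 1L)
}

rand_bases <- function(n, gc = 0.5) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# Random fill guaranteed to contain no ATG in any frame: spurious start
# codons are removed by point substitution (rejection-style fix-up).
filler_bases <- function(n, gc = 0.5) {
  x <- rand_bases(n, gc)
  repeat {
    s <- paste(x, collapse = "")
    hit <- regexpr("ATG", s, fixed = TRUE)
    if (hit == -1) return(x)
    x[as.integer(hit) + 1L] <- "C"
  }
}

# An ORF string of the given length (multiple of 3, >= 6): ATG, a body with
# no in-frame stop and no ATG in any frame, and a stop codon chosen so that
# the body/stop boundary cannot spell ATG.
make_orf_string <- function(len, gc = 0.5) {
  stopifnot(len >= 6, len %% 3 == 0)
  codon_alphabet <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                      c("A","C","G","T")), 1, paste, collapse = "")
  allowed <- setdiff(codon_alphabet, c(STOP_CODONS, "ATG"))
  k <- len %/% 3L - 2L
  body <- if (k > 0) sample(allowed, k, replace = TRUE) else character(0)
  for (iter in seq_len(1000)) {
    s <- paste(body, collapse = "")
    hit <- regexpr("ATG", s, fixed = TRUE)
    if (hit == -1) break
    body[((as.integer(hit) - 1L) %/% 3L) + 1L] <- sample(allowed, 1L)
  }
  tail2 <- if (k > 0) substr(paste(body, collapse = ""), 3 * k - 1, 3 * k) else "TG"
  stops <- STOP_CODONS[!grepl("ATG", paste0(tail2, STOP_CODONS), fixed = TRUE)]
  paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
}

frame_fit_end <- function(cds_start, target_end) {
  cds_start + 3L * ((target_end - cds_start + 1L) %/% 3L) - 1L
}

# Blueprint per architecture label: exon partition, CDS coordinates and any
# additional planted ORF intervals. Optional exon_lengths override is
# feasibility-checked against the label's minimum exon sizes.
blueprint <- function(label, exon_lengths = NULL) {
  minima <- switch(label,
    MONO_IMMUNE = 300L,
    CLASSIC_PTC = c(150L, 150L, 120L),
    BICISTRONIC_3PRIME = c(120L, 200L, 150L),
    STOP_NEAR_JUNCTION = c(150L, 100L),
    ATG_EXON1 = c(150L, 100L, 150L),
    NO_UORF = c(100L, 150L, 150L),
    UORF_IMMUNE = c(150L, 100L, 200L),
    UORF_ELICITING = c(220L, 100L, 200L),
    MULTI_ORF_RESCUE = c(120L, 160L, 200L, 150L)
  )
  if (is.null(exon_lengths)) {
    exon_lengths <- purrr::map_int(minima, ~ r_int(.x, .x + 100L))
  } else {
    exon_lengths <- as.integer(exon_lengths)
    if (length(exon_lengths) != length(minima) || any(exon_lengths < minima)) {
      rlang::abort(paste0("fixture generation: exon_lengths infeasible for ",
                          label, " (need ", length(minima), " exons of at least ",
                          paste(minima, collapse = ","), " nt)"))
    }
  }
  e <- exon_lengths
  j <- cumsum(e)
  L <- j[length(j)]
  extra <- list()
  if (label == "MONO_IMMUNE") {
    cs <- r_int(20L, 50L)
    k <- r_int(30L, (L - 10L - cs + 1L) %/% 3L)
    ce <- cs + 3L * k - 1L
  } else if (label == "CLASSIC_PTC") {
    cs <- r_int(15L, 60L)
    ce <- frame_fit_end(cs, j[2] - 56L - r_int(10L, 30L))
  } else if (label == "BICISTRONIC_3PRIME") {
    cs <- r_int(15L, 50L)
    ce <- frame_fit_end(cs, j[1] + r_int(30L, e[2] - 130L))
    end_o <- j[2] - 55L + r_int(15L, 45L)
    k <- r_int(20L, (end_o - ce - 2L) %/% 3L)
    extra <- list(c(end_o - 3L * k + 1L, end_o))
  } else if (label == "STOP_NEAR_JUNCTION") {
    ce <- j[1] - 45L
    k <- r_int(20L, (ce - 10L) %/% 3L)
    cs <- ce - 3L * k + 1L
  } else if (label == "ATG_EXON1") {
    cs <- r_int(15L, 60L)
    ce <- frame_fit_end(cs, j[2] + r_int(20L, e[3] - 20L))
  } else if (label == "NO_UORF") {
    cs <- j[1] + r_int(10L, e[2] - 60L)
    ce <- frame_fit_end(cs, j[2] + r_int(20L, e[3] - 20L))
  } else if (label %in% c("UORF_IMMUNE", "UORF_ELICITING")) {
    if (label == "UORF_IMMUNE") {
      end_u <- j[2] - r_int(10L, 50L)
      kmin <- max(34L, ceiling((end_u - j[1] + 11L) / 3))
      k <- r_int(kmin, (end_u - 9L) %/% 3L)
    } else {
      end_u <- j[1] - 56L - r_int(5L, 30L)
      k <- r_int(10L, (end_u - 9L) %/% 3L)
    }
    extra <- list(c(end_u - 3L * k + 1L, end_u))
    cs <- j[2] + r_int(5L, 15L)
    k2 <- r_int(20L, (L - 5L - cs + 1L) %/% 3L)
    ce <- cs + 3L * k2 - 1L
  } else if (label == "MULTI_ORF_RESCUE") {
    cs <- r_int(15L, 50L)
    ce <- frame_fit_end(cs, j[1] + r_int(30L, e[2] - 120L))
    end_a <- j[2] - 55L + r_int(15L, 40L)
    ka <- r_int(15L, (end_a - ce - 2L) %/% 3L)
    end_b <- j[3] - 55L + r_int(15L, 40L)
    kb <- r_int(15L, min(40L, (end_b - j[2] - 2L) %/% 3L))
    extra <- list(c(end_a - 3L * ka + 1L, end_a),
                  c(end_b - 3L * kb + 1L, end_b))
  }
  list(exon_lengths = e, cds_start = cs, cds_end = ce, extra_orfs = extra)
}

assemble_sequence <- function(bp, gc = 0.5) {
  L <- sum(bp$exon_lengths)
  chars <- filler_bases(L, gc)
  planted <- c(list(c(bp$cds_start, bp$cds_end)), bp$extra_orfs)
  for (iv in planted) {
    chars[iv[1]:iv[2]] <- seqinr::s2c(make_orf_string(iv[2] - iv[1] + 1L, gc))
  }
  in_planted <- rep(FALSE, L)
  for (iv in planted) in_planted[iv[1]:iv[2]] <- TRUE
  allowed_starts <- purrr::map_int(planted, 1)
  # remove start codons created across segment boundaries
  for (iter in seq_len(200)) {
    s <- paste(chars, collapse = "")
    hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    hits <- hits[hits != -1 & !(hits %in% allowed_starts)]
    if (length(hits) == 0) break
    p <- hits[1]
    mutable <- (p:(p + 2L))[!in_planted[p:(p + 2L)]]
    if (length(mutable) == 0) {
      rlang::abort("fixture generation: cannot remove spurious ATG")
    }
    chars[mutable[1]] <- "C"
  }
  paste(chars, collapse = "")
}

#' Generate one labeled synthetic transcript
#'
#' Builds a transcript whose architecture provably belongs to the requested
#' label: exon lengths, the annotated CDS and any planted rescuing ORFs or
#' uORFs are placed by construction (the STOP_NEAR_JUNCTION label plants
#' the stop exactly 45 nt upstream of the terminal junction, the distance
#' of the known SNURF architecture), and the remaining sequence is random
#' fill kept free of start codons by rejection-style substitution — the
#' reason generation can fail for very small exons. Before a transcript is
#' emitted the package's own classifiers are run on it and the result is
#' checked against the label (self-check loop; a handful of attempts are
#' made before giving up).
#'
#' @param label One of `r paste(ARCHITECTURE_LABELS, collapse=", ")`.
#' @param seed Optional integer seed (sets the RNG for this call).
#' @param gc GC content of the random fill (default 0.5).
#' @param exon_lengths Optional exon-partition override; infeasible
#'   partitions (wrong exon count or exons below the label's minima) are a
#'   generation error.
#' @return A one-row transcript table with an extra `label` column.
#' @export
make_transcript <- function(label, seed = NULL, gc = 0.5,
                            exon_lengths = NULL) {
  label <- match.arg(label, ARCHITECTURE_LABELS)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(20)) {
    bp <- blueprint(label, exon_lengths)
    seq <- assemble_sequence(bp, gc)
    tx <- transcripts(paste0("SYN_", label), seq, list(bp$exon_lengths),
                      bp$cds_start, bp$cds_end)
    got <- predict_architecture(tx)$architecture
    if (got == label) {
      tx$label <- label
      return(tx)
    }
  }
  rlang::abort(paste0("fixture generation: could not realize label ", label,
                      " after 20 attempts"))
}

#' Generate a labeled synthetic transcript set
#'
#' @param n_per_label Transcripts per label.
#' @param labels Labels to generate (default: all nine architecture
#'   classes).
#' @param seed Integer seed; the whole set is deterministic given
#'   (`labels`, `n_per_label`, `seed`, `gc`).
#' @param gc GC content of the random fill.
#' @return A transcript table with `label` column; ids are
#'   `SYN_<label>_<k>`.
#' @export
make_transcripts <- function(n_per_label = 10L, labels = ARCHITECTURE_LABELS,
                             seed = 1L, gc = 0.5) {
  set.seed(seed)
  out <- purrr::map_dfr(labels, function(lab) {
    purrr::map_dfr(seq_len(n_per_label), function(k) {
      tx <- make_transcript(lab, gc = gc)
      tx$id <- sprintf("SYN_%s_%03d", lab, k)
      tx
    })
  })
  out
}

#' Simulate a GINI expression experiment
#'
#' Emulates a control vs NMD-inhibition comparison: per-probe log-normal
#' intensities (probe baselines drawn once, arm noise per sample), with the
#' inhibited-arm mean of "sensitive" probes multiplied by `fold_change` —
#' the accumulation an NMD substrate shows when decay is blocked.
#' Deterministic under `seed`.
#'
#' @param n_probes Total probes.
#' @param n_sensitive Number of planted NMD-sensitive probes (the first
#'   `n_sensitive` probe ids).
#' @param fold_change Multiplicative increase under inhibition for
#'   sensitive probes; must be >= 1 (1.0 makes every probe null, for
#'   type-I-rate studies).
#' @param n_per_arm Samples per arm (>= 2).
#' @param seed Optional integer seed.
#' @param meanlog,sdlog Log-normal intensity parameters (natural-log
#'   scale); defaults 6 and 0.25.
#' @return A list: `expr` (long tibble `probe_id`, `sample`, `value`),
#'   `groups` (`sample`, `group`), `truth` (`probe_id`, `sensitive`).
#' @export
make_expression <- function(n_probes, n_sensitive, fold_change,
                            n_per_arm = 4L, seed = NULL,
                            meanlog = 6, sdlog = 0.25) {
  if (n_per_arm < 2) rlang::abort("make_expression: n_per_arm must be >= 2")
  if (fold_change < 1) rlang::abort("make_expression: fold_change must be >= 1")
  if (n_sensitive > n_probes) rlang::abort("make_expression: n_sensitive > n_probes")
  if (!is.null(seed)) set.seed(seed)
  probe_id <- sprintf("P%05d", seq_len(n_probes))
  sensitive <- seq_len(n_probes) <= n_sensitive
  samples_c <- sprintf("CTRL_%02d", seq_len(n_per_arm))
  samples_i <- sprintf("INHI_%02d", seq_len(n_per_arm))
  base <- stats::rnorm(n_probes, meanlog, 0.5)
  rows <- purrr::map_dfr(seq_len(n_probes), function(p) {
    ctl <- exp(stats::rnorm(n_per_arm, base[p], sdlog))
    inh <- exp(stats::rnorm(n_per_arm, base[p], sdlog)) *
      ifelse(sensitive[p], fold_change, 1)
    tibble::tibble(probe_id = probe_id[p],
                   sample = c(samples_c, samples_i),
                   value = c(ctl, inh))
  })
  list(expr = rows,
       groups = tibble::tibble(sample = c(samples_c, samples_i),
                               group = rep(c("control", "inhibited"),
                                           each = n_per_arm)),
       truth = tibble::tibble(probe_id = probe_id, sensitive = sensitive))
}
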