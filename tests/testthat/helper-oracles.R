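# Independent oracles and hand-built deterministic fixtures.

# Brute-force ORF enumeration: every (start, end) pair with ATG at start,
# a stop codon at the end, frame-consistent length, no in-frame stop
# strictly inside, entirely within [from, to]. Checks all candidate ends
# rather than jumping to the first stop.
brute_orf_scan <- function(seq, from = 1, to = nchar(seq), min_length = 6) {
  seq <- toupper(seq)
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  s <- from
  while (s <= to - 5) {
    if (substr(seq, s, s + 2) == "ATG") {
      e <- s + 5
      while (e <= to) {
        if (substr(seq, e - 2, e) %in% stops) {
          internal <- FALSE
          p <- s + 3
          while (p <= e - 5) {
            if (substr(seq, p, p + 2) %in% stops) { internal <- TRUE; break }
            p <- p + 3
          }
          if (!internal && (e - s + 1) >= min_length) {
            res[[length(res) + 1]] <- c(s, e)
          }
        }
        e <- e + 3
      }
    }
    s <- s + 1
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("start", "end")
  out[order(out$start, out$end), , drop = FALSE]
}

# Textbook Welch t-test: statistic, Welch-Satterthwaite df, two-sided p.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}

# Literal standard genetic code, written out entry by entry.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

translate_oracle <- function(seq) {
  starts <- seq.int(1, nchar(seq) - 2, by = 3)
  paste(CODON_TABLE[substring(seq, starts, starts + 2)], collapse = "")
}

# Deterministic hand-built transcript: an all-C backbone (which can spell
# neither ATG nor a stop codon) with ORFs of the form ATG (GCC)* TAA
# planted at exact coordinates, and an A placed at -3 of each ORF so its
# Kozak context is positive.
plant_orf_str <- function(len) {
  stopifnot(len >= 6, len %% 3 == 0)
  paste0("ATG", strrep("GCC", (len - 6) / 3), "TAA")
}

planted_transcript <- function(id, exon_lengths, cds = NULL, orfs = list()) {
  L <- sum(exon_lengths)
  chars <- rep("C", L)
  for (iv in c(if (!is.null(cds)) list(cds), orfs)) {
    s <- iv[1]; e <- iv[2]
    chars[s:e] <- strsplit(plant_orf_str(e - s + 1), "")[[1]]
    if (s >= 4) chars[s - 3] <- "A"
  }
  transcripts(id, paste(chars, collapse = ""), list(exon_lengths),
              if (is.null(cds)) NA else cds[1],
              if (is.null(cds)) NA else cds[2])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
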