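test_that("the classic 55-nt rule separates eliciting from immune stops", {
  mk <- function(exons, ce) {
    planted_transcript("t", exons, cds = c(ce - 89, ce))
  }
  # SNURF-like: stop 45 nt upstream of the terminal junction is immune
  expect_equal(classify_classic(mk(c(200, 100), 155))$status, "IMMUNE")
  # stop inside the terminal exon
  v <- classify_classic(mk(c(200, 100), 230))
  expect_equal(v$status, "IMMUNE")
  expect_lt(v$stop_to_terminal_junction, 0)
  # boundary: 56 elicits, 55 is immune under the default strict comparator
  expect_equal(classify_classic(mk(c(200, 100), 144))$status, "ELICITING")
  expect_equal(classify_classic(mk(c(200, 100), 145))$status, "IMMUNE")
  expect_equal(classify_classic(mk(c(200, 100), 145), comparator = "ge")$status,
               "ELICITING")
  # single-exon transcripts have no junction and are immune
  mono <- planted_transcript("m", 300, cds = c(21, 110))
  expect_equal(classify_classic(mono)$status, "IMMUNE")
  expect_error(classify_classic(transcripts("x", strrep("C", 9), list(9))),
               "missing CDS")
  # status IMMUNE iff no junction keeps its EJC
  for (ce in c(144, 145, 230)) {
    v <- classify_classic(mk(c(200, 100), ce))
    expect_equal(v$status == "IMMUNE",
                 length(v$unneutralized_junctions[[1]]) == 0)
  }
})

test_that("classification is monotone in the threshold", {
  set.seed(201)
  for (k in 1:25) {
    exons <- sample(80:300, sample(2:4, 1), replace = TRUE)
    L <- sum(exons)
    ce <- sample(95:L, 1)
    tx <- planted_transcript("t", exons, cds = c(ce - 89, ce))
    prev <- classify_classic(tx, threshold = 0)$status
    for (th in c(10, 55, 100, 200, 400)) {
      cur <- classify_classic(tx, threshold = th)$status
      # raising the threshold never converts IMMUNE -> ELICITING
      expect_false(prev == "IMMUNE" && cur == "ELICITING")
      prev <- cur
    }
  }
})

test_that("junction neutralization is the stated window arithmetic", {
  expect_true(neutralizes(10, 200, 150))    # ORF reads across the junction
  expect_true(neutralizes(10, 100, 150))    # ends 50 nt upstream (<= 55)
  expect_false(neutralizes(10, 90, 150))    # ends 60 nt upstream (> 55)
  expect_false(neutralizes(160, 300, 150))  # starts downstream of the junction
  expect_equal(neutralizes(c(10, 10), c(100, 90), 150), c(TRUE, FALSE))
})

test_that("rescue search finds single-ORF units in the penultimate exon", {
  # stop in the penultimate exon, > 55 nt upstream; a rescuing ORF starting
  # and ending in the penultimate exon within 55 nt of the terminal junction
  tx <- planted_transcript("t", c(300, 100), cds = c(21, 110),
                           orfs = list(c(150, 260)))
  units <- find_rescue_units(tx)
  expect_equal(nrow(units), 1L)
  expect_equal(units$unit_size, 1L)
  expect_equal(units$start, 150L)
  expect_equal(units$neutralized[[1]], 300L)

  # no ATG in the 3' UTR: no unit
  bare <- planted_transcript("t", c(300, 100), cds = c(21, 110))
  expect_equal(nrow(find_rescue_units(bare)), 0L)

  # an already-immune transcript yields no rows rather than an error
  ok <- planted_transcript("t", c(300, 100), cds = c(21, 290))
  expect_equal(nrow(find_rescue_units(ok)), 0L)
})

test_that("jointly required ORFs are reported as one unit", {
  # bicistronic-like: annotated CDS covers junctions 1-2; one downstream ORF
  # spans junction 3 -> a single-ORF unit
  tx1 <- planted_transcript("lass1_gdf1_like", c(150, 150, 150, 150),
                            cds = c(21, 320), orfs = list(c(380, 490)))
  u1 <- find_rescue_units(tx1)
  expect_equal(unique(u1$unit_size), 1L)

  # two downstream junctions, each neutralized by a different ORF: the
  # minimal cover is the pair, reported as one unit of size 2
  tx2 <- planted_transcript("t", c(200, 200, 200, 200), cds = c(21, 260),
                            orfs = list(c(300, 410), c(500, 619)))
  u2 <- find_rescue_units(tx2)
  expect_equal(unique(u2$unit), 1L)
  expect_equal(unique(u2$unit_size), 2L)
  expect_setequal(u2$start, c(300L, 500L))
  expect_setequal(sort(unique(unlist(u2$neutralized))), c(400L, 600L))

  # exhaustive subset check: the implementation's units equal the minimal
  # covering subsets computed directly from scan_orfs + neutralizes
  required <- classify_classic(tx2)$unneutralized_junctions[[1]]
  orfs <- scan_orfs(tx2, region = "3utr")
  covers <- lapply(seq_len(nrow(orfs)), function(i) {
    required[neutralizes(orfs$start[i], orfs$end[i], required)]
  })
  all_covering <- list()
  for (k in seq_len(min(3, nrow(orfs)))) {
    for (ss in utils::combn(nrow(orfs), k, simplify = FALSE)) {
      if (all(required %in% unlist(covers[ss]))) {
        all_covering[[length(all_covering) + 1]] <- ss
      }
    }
  }
  minimal <- Filter(function(ss) {
    !any(vapply(all_covering, function(o) {
      length(o) < length(ss) && all(o %in% ss)
    }, logical(1)))
  }, all_covering)
  expect_equal(length(unique(u2$unit)), length(minimal))
})

test_that("adding a 3'-UTR ORF can only shrink the surviving junction set", {
  surviving <- function(tx, orf_tbl) {
    req <- classify_classic(tx)$unneutralized_junctions[[1]]
    if (nrow(orf_tbl) == 0) return(req)
    req[!vapply(req, function(j) {
      any(neutralizes(orf_tbl$start, orf_tbl$end, j))
    }, logical(1))]
  }
  tx <- planted_transcript("t", c(200, 200, 200, 200), cds = c(21, 260),
                           orfs = list(c(300, 410)))
  one <- scan_orfs(tx, region = "3utr")
  tx2 <- planted_transcript("t", c(200, 200, 200, 200), cds = c(21, 260),
                            orfs = list(c(300, 410), c(500, 619)))
  both <- scan_orfs(tx2, region = "3utr")
  expect_true(all(surviving(tx2, both) %in% surviving(tx, one)))
  expect_true(all(surviving(tx, one) %in% surviving(tx, one[0, ])))
})

test_that("5'-UTR classes follow the scanning-ribosome ledger", {
  # annotated ATG in exon 1
  a <- planted_transcript("a", c(150, 150), cds = c(30, 119))
  expect_equal(classify_five_prime(a)$class, "ATG_IN_FIRST_EXON")

  # ATG in exon 2, no upstream ATG: scanning removes every upstream EJC
  b <- planted_transcript("b", c(100, 200), cds = c(150, 239))
  expect_equal(classify_five_prime(b)$class, "NO_UORF")

  # ATG in exon 3; single uORF wholly in exon 1 ending > 55 nt before
  # junction 1: the EJCs of junctions 1 and 2 survive
  c1 <- planted_transcript("c", c(200, 150, 150), cds = c(380, 469),
                           orfs = list(c(20, 100)))
  v1 <- classify_five_prime(c1)
  expect_equal(v1$class, "UORF_ELICITING")
  expect_setequal(v1$unneutralized_junctions[[1]], c(200L, 350L))

  # same geometry but the uORF spans junction 1 and ends within 55 nt of
  # junction 2: all EJCs between the uORF end and the ATG are removed
  c2 <- planted_transcript("c", c(200, 150, 150), cds = c(380, 469),
                           orfs = list(c(100, 330)))
  expect_equal(classify_five_prime(c2)$class, "UORF_IMMUNE")

  expect_error(classify_five_prime(transcripts("x", strrep("C", 9), list(9))),
               "missing CDS")
})

test_that("5'-UTR classes partition any transcript set", {
  tx <- make_transcripts(n_per_label = 3, seed = 7)
  cls <- classify_five_prime(tx)
  expect_equal(nrow(cls), nrow(tx))
  expect_true(all(cls$class %in% c("ATG_IN_FIRST_EXON", "NO_UORF",
                                   "UORF_IMMUNE", "UORF_ELICITING")))
  expect_false(anyNA(cls$class))
})

test_that("the ATG exon census counts and percentages are consistent", {
  pub <- census_from_counts(refseq_atg_census_2010())
  expect_equal(sum(pub$n), 30035L)
  expect_equal(round(pub$pct[pub$exon == 1], 1), 59.0)

  one <- atg_exon_census(planted_transcript("t", c(150, 150), cds = c(30, 119)))
  expect_equal(one$n, 1L)
  expect_equal(one$pct, 100)

  tx <- make_transcripts(n_per_label = 2, seed = 11)
  cen <- atg_exon_census(tx)
  expect_equal(sum(cen$n), nrow(tx))
  expect_equal(sum(cen$pct), 100)
})
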