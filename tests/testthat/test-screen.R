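test_that("empty input yields an empty screen, not an error", {
  scr <- screen_pipeline(transcripts(character(0), character(0), list()))
  expect_s3_class(scr, "nmd_screen")
  expect_equal(nrow(scr$transcripts), 0L)
  expect_equal(nrow(tidy(scr)), 0L)
})

test_that("the screen recovers planted architecture labels exactly", {
  tx <- make_transcripts(n_per_label = 4, seed = 21)
  scr <- screen_pipeline(tx)
  got <- dplyr::left_join(tx[, c("id", "label")], scr$transcripts, by = "id")
  expect_equal(got$architecture, got$label)
  # funnel counts equal the planted class sizes
  f <- glance(scr)
  expect_equal(f$input, nrow(tx))
  expect_equal(f$classic_eliciting,
               sum(tx$label %in% c("CLASSIC_PTC", "BICISTRONIC_3PRIME",
                                   "MULTI_ORF_RESCUE")))
  expect_equal(f$five_prime_no_uorf, sum(tx$label == "NO_UORF"))
  expect_equal(f$five_prime_uorf_eliciting, sum(tx$label == "UORF_ELICITING"))
  expect_equal(f$rescued_transcripts,
               sum(tx$label %in% c("BICISTRONIC_3PRIME", "MULTI_ORF_RESCUE")))
})

test_that("evidence tables drive the candidate verdicts", {
  tx <- planted_transcript("bi", c(300, 100), cds = c(21, 110),
                           orfs = list(c(150, 260)))
  gene_ids <- c(bi = "GENE1")
  q <- "bi:150:260"
  protein_hits <- tibble::tibble(query_id = q, positives = 30,
                                 align_length = 33,
                                 orf_protein_length = 36)
  scr <- screen_pipeline(tx, gene_ids = gene_ids, protein_hits = protein_hits)
  cand <- tidy(scr)
  expect_equal(nrow(cand), 1L)
  expect_true(cand$kozak)
  expect_equal(cand$similarity, "KEEP")
  expect_true(cand$protein_evidence)
  expect_true(cand$candidate)

  # a strong same-gene nucleotide hit discards the candidate
  nhits <- tibble::tibble(query_id = q, subject_gene_id = "GENE1",
                          evalue = 1e-9, coverage_fraction = 0.9)
  scr2 <- screen_pipeline(tx, gene_ids = gene_ids, protein_hits = protein_hits,
                          nucleotide_hits = nhits)
  expect_equal(tidy(scr2)$similarity, "DISCARD")
  expect_false(tidy(scr2)$candidate)
  expect_equal(glance(scr2)$final_candidates, 0L)

  # without any evidence tables no candidate reaches a positive verdict
  scr3 <- screen_pipeline(tx, gene_ids = gene_ids)
  expect_false(any(tidy(scr3)$candidate))
})

test_that("the functional-uORF length filter is strict by default", {
  # UORF_IMMUNE fixture with a planted uORF of exactly 99 nt
  tx <- planted_transcript("u", c(200, 100, 200), cds = c(310, 399),
                           orfs = list(c(160, 258)))
  expect_equal(classify_five_prime(tx)$class, "UORF_IMMUNE")
  scr <- screen_pipeline(tx)
  expect_equal(sum(tidy(scr)$branch == "5UTR"), 0L)
  scr_ge <- screen_pipeline(tx, screen_config(uorf_comparator = "ge"))
  expect_equal(sum(tidy(scr_ge)$branch == "5UTR"), 1L)
})

test_that("configs round-trip through YAML and reject unknown keys", {
  cfg <- screen_config(threshold = 50, min_uorf_length = 120,
                       comparator = "ge")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(threshold = 50, min_uorf_length = 120,
                        comparator = "ge"), path)
  got <- read_screen_config(path)
  expect_equal(unclass(got), unclass(cfg))
  yaml::write_yaml(list(not_a_key = 1), path)
  expect_error(read_screen_config(path), "unknown config key")
})

test_that("tidy, glance, print and autoplot expose the screen results", {
  tx <- make_transcripts(n_per_label = 1, seed = 31)
  scr <- screen_pipeline(tx)
  expect_s3_class(tidy(scr), "tbl_df")
  expect_equal(nrow(glance(scr)), 1L)
  expect_output(print(scr), "nmd_screen")
  expect_s3_class(autoplot(scr), "ggplot")
  expect_s3_class(autoplot(atg_exon_census(tx)), "ggplot")
  expect_s3_class(plot_transcript_map(tx[1, ]), "ggplot")
})
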