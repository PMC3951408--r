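test_that("the Welch test handles identical and degenerate groups", {
  a <- c(3.2, 4.1, 3.8, 3.5)
  expect_equal(welch_t_test(a, a)$p_value, 1)
  expect_equal(welch_t_test(c(10, 10, 10), c(10, 10, 10))$p_value, 1)
  expect_equal(welch_t_test(c(10, 10, 10), c(12, 12, 12))$p_value, 0)
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
  expect_error(welch_t_test(c(1, NA, 2), c(1, 2)), ">= 2")
})

test_that("the Welch test equals the textbook formula, and is symmetric", {
  set.seed(401)
  for (k in 1:50) {
    a <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    expect_equal(welch_t_test(a, b)$p_value, welch_oracle(a, b),
                 tolerance = 1e-12)
    expect_equal(welch_t_test(a, b)$p_value, welch_t_test(b, a)$p_value)
    # invariance under a common shift of both groups
    expect_equal(welch_t_test(a + 5, b + 5)$p_value,
                 welch_t_test(a, b)$p_value, tolerance = 1e-9)
  }
})

test_that("GINI verdicts combine significance and direction", {
  v <- gini_verdict(c(0.001, 0.8, 0.001), c(5, 5, 5), c(9, 9, 2))
  expect_equal(v$verdict, c("NMD_SENSITIVE", "NMD_INSENSITIVE", "INCONCLUSIVE"))
  expect_equal(v$direction, c("UP_ON_INHIBITION", "UP_ON_INHIBITION", "DOWN"))
  # a sensitive call always has the stabilization direction
  set.seed(402)
  p <- runif(200); mc <- rnorm(200); mi <- rnorm(200)
  vv <- gini_verdict(p, mc, mi)
  expect_true(all(vv$direction[vv$verdict == "NMD_SENSITIVE"] == "UP_ON_INHIBITION"))
  expect_true(all(p[vv$verdict == "NMD_SENSITIVE"] < 0.05))
})

test_that("per-probe verdict tables work end to end with exclusions", {
  sim <- make_expression(n_probes = 20, n_sensitive = 5, fold_change = 6,
                         n_per_arm = 5, seed = 403)
  expr <- dplyr::mutate(sim$expr,
                        gene_id = sub("^P", "G", probe_id),
                        unique_gene = probe_id != "P00006")
  out <- gini_verdicts(expr, sim$groups)
  expect_equal(nrow(out), 20L)
  expect_true(is.na(out$verdict[out$probe_id == "P00006"]))
  expect_true(out$excluded[out$probe_id == "P00006"])
  # strong planted effects are called sensitive
  called <- out$verdict[out$probe_id %in% sprintf("P%05d", 1:5) & !out$excluded]
  expect_true(all(called == "NMD_SENSITIVE"))
  expect_equal(unique(out$scale), "log2")
  # groups must cover all samples
  expect_error(gini_verdicts(expr, sim$groups[-1, ]), "group")
})

test_that("simulated GINI verdicts recover planted labels accurately", {
  sim <- make_expression(n_probes = 500, n_sensitive = 250, fold_change = 2,
                         n_per_arm = 4, seed = 404)
  out <- gini_verdicts(sim$expr, sim$groups)
  joined <- dplyr::left_join(out, sim$truth, by = "probe_id")
  sens <- mean(joined$verdict[joined$sensitive] == "NMD_SENSITIVE")
  spec <- mean(joined$verdict[!joined$sensitive] == "NMD_INSENSITIVE")
  expect_gte((sens + spec) / 2, 0.8)
})

test_that("expression fixtures validate their arguments and determinism", {
  expect_error(make_expression(10, 2, 2, n_per_arm = 1), "n_per_arm")
  expect_error(make_expression(10, 2, 0.5), "fold_change")
  expect_error(make_expression(10, 20, 2), "n_sensitive")
  a <- make_expression(15, 3, 2, seed = 405)
  b <- make_expression(15, 3, 2, seed = 405)
  expect_identical(a, b)
  z <- make_expression(10, 0, 2, seed = 406)
  expect_false(any(z$truth$sensitive))
})

test_that("expression tables round-trip through the TSV reader", {
  sim <- make_expression(6, 2, 3, n_per_arm = 3, seed = 407)
  wide <- tidyr::pivot_wider(sim$expr, names_from = "sample",
                             values_from = "value")
  ep <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wide, ep)
  readr::write_tsv(sim$groups, gp)
  dat <- read_expression(ep, gp)
  v1 <- gini_verdicts(dat$expr, dat$groups)
  v2 <- gini_verdicts(sim$expr, sim$groups)
  expect_equal(v1$p_value, v2$p_value)
})

test_that("TIS matching distinguishes exact, partial and absent support", {
  pred <- tibble::tibble(
    transcript_id = c("NM_001003680", "NM_018848", "C19orf48_tx", "C19orf48_tx", "lonely"),
    start = c(74L, 261L, 139L, 337L, 10L),
    length = c(111L, 192L, 105L, 42L, 30L))
  tis <- tibble::tibble(
    transcript_id = c("NM_001003680", "NM_018848", "C19orf48_tx"),
    start = c(74L, 261L, 337L),
    length = c(111L, 192L, 42L))
  got <- match_tis(pred, tis)
  expect_equal(got$match_type[got$transcript_id == "NM_001003680"], "EXACT")
  expect_equal(got$match_type[got$transcript_id == "NM_018848"], "EXACT")
  # two predicted rescuers, only one TIS verified
  expect_equal(unique(got$match_type[got$transcript_id == "C19orf48_tx"]),
               "PARTIAL")
  expect_equal(got$match_type[got$transcript_id == "lonely"], "NONE")

  empty <- match_tis(pred, tis[0, ])
  expect_true(all(empty$match_type == "NONE"))
  expect_error(match_tis(rbind(pred, pred[1, ]), tis), "duplicate")
})
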