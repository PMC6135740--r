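test_that("lineage ANOVA p-values are uniform under the null", {
  set.seed(21)
  d <- make_design(E = 9, n_per = 2)
  Y <- matrix(rnorm(1000 * d$n), 1000,
              dimnames = list(sprintf("f%04d", 1:1000), NULL))
  tests <- lineageseq:::.lineage_tests_labels(Y, d$embryo, d$lineage)
  ks <- suppressWarnings(ks.test(tests$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  # binomial calibration of the rejection rate
  for (alpha in c(0.01, 0.05)) {
    se <- sqrt(alpha * (1 - alpha) / nrow(tests))
    expect_lt(abs(mean(tests$p < alpha) - alpha), 3 * se)
  }
})

test_that("a strong planted effect is detected and constants are skipped", {
  set.seed(22)
  d <- make_design(E = 9, n_per = 2)
  y <- rnorm(d$n) + ifelse(d$lineage == "A", 2, -2)  # 4 sd shift
  out <- anova_lineage(y, d$embryo, d$lineage)
  expect_lt(out$p, 0.001)
  expect_null(anova_lineage(rep(1, d$n), d$embryo, d$lineage))
})

test_that("BH q-values match the step-up oracle and stay monotone", {
  expect_equal(compute_q(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(compute_q(rep(1, 5)), rep(1, 5))
  expect_equal(compute_q(0.2), 0.2)
  set.seed(23)
  p <- sort(runif(100))
  q <- compute_q(p)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q >= p - 1e-12))
  qs <- compute_q(p, method = "storey")
  expect_true(all(qs <= q + 1e-12))
})

test_that("shuffled background is deterministic and validates its arguments", {
  cfg <- synthetic_config(seed = 24, n_genes = 100)
  sim <- simulate_cells_and_expression(cfg)
  b1 <- shuffle_background(sim$fpkm, sim$cells, "four_cell", 2, seed = 5)
  b2 <- shuffle_background(sim$fpkm, sim$cells, "four_cell", 2, seed = 5)
  expect_identical(b1, b2)
  expect_length(b1, 200)
  expect_error(shuffle_background(sim$fpkm, sim$cells, "four_cell", 0, 1),
               "at least 1")
})

test_that("real and background distributions agree on null data", {
  # On the global null the p ensembles must be indistinguishable. The real
  # and shuffled tests share the same expression values, so the nominal
  # two-sample KS p is approximate under that dependence: assert no gross
  # separation per seed and a comfortable median across seeds. The q
  # ensembles both collapse onto atoms near 1 (a BH step-up property under
  # the null), so they are compared on location.
  ksp <- vapply(1:3, function(s) {
    cfg <- synthetic_config(seed = 30 + s, n_genes = 2000,
                            frac_lineage_genes = 0)
    sim <- simulate_cells_and_expression(cfg)
    tests <- lineage_tests(sim$fpkm, sim$cells, "four_cell")
    bg_p <- shuffle_background(sim$fpkm, sim$cells, "four_cell", 1, seed = s,
                               value = "p")
    bg_q <- shuffle_background(sim$fpkm, sim$cells, "four_cell", 1, seed = s)
    expect_gt(median(tests$q), 0.9)
    expect_gt(median(bg_q), 0.9)
    expect_equal(sum(tests$q < 0.01), 0)
    expect_equal(sum(bg_q < 0.01), 0)
    compare_distributions(tests$p, bg_p)$ks_p
  }, numeric(1))
  expect_gt(min(ksp), 1e-4)
  expect_gt(median(ksp), 0.05)
})

test_that("distribution comparison has the analytic KS gap and rejects empties", {
  set.seed(26)
  a <- runif(10000, 0, 0.5)
  b <- runif(10000, 0, 1)
  cmp <- compare_distributions(a, b)
  expect_lt(abs(cmp$ks_stat - 0.5), 0.03)
  expect_equal(cmp$n_real, 10000)

  same <- runif(100)
  expect_equal(compare_distributions(same, same)$ks_stat, 0)
  expect_error(compare_distributions(numeric(0), runif(5)), "empty")
})

test_that("separation from the background grows with the planted effect size", {
  meds <- vapply(c(0, 1, 2, 4), function(eff) {
    ksp <- vapply(1:5, function(s) {
      cfg <- synthetic_config(seed = 40 + s, n_genes = 500,
                              lineage_effect = eff,
                              frac_lineage_genes = if (eff == 0) 0 else 0.1)
      sim <- simulate_cells_and_expression(cfg)
      tests <- lineage_tests(sim$fpkm, sim$cells, "four_cell")
      bg <- shuffle_background(sim$fpkm, sim$cells, "four_cell", 1, seed = s,
                               value = "p")
      compare_distributions(tests$p, bg)$ks_p
    }, numeric(1))
    median(ksp)
  }, numeric(1))
  expect_true(all(diff(meds) <= 0))
  expect_lt(meds[4], meds[1])
})
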