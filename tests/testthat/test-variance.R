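test_that("hand-computed nested decomposition is reproduced", {
  # embryo1 lineage means (1, 3), embryo2 (2, 4), 2 cells each, no noise
  y <- c(1, 1, 3, 3, 2, 2, 4, 4)
  d <- make_design(E = 2, n_per = 2)
  vp <- decompose_gene(y, d$embryo, d$lineage)
  expect_equal(vp$ss_embryo, 2)
  expect_equal(vp$ss_lineage, 8)
  expect_equal(vp$ss_residual, 0)
  expect_equal(vp$r, 0.8)
})

test_that("constant features have zero sums of squares and undefined r", {
  d <- make_design(E = 3)
  vp <- decompose_gene(rep(5, d$n), d$embryo, d$lineage)
  expect_equal(vp$ss_embryo, 0)
  expect_equal(vp$ss_lineage, 0)
  expect_true(is.na(vp$r))
})

test_that("design preconditions are enforced", {
  expect_error(decompose_gene(1:4, rep("E1", 4), c("A", "A", "B", "B")),
               "at least 2 embryos")
  expect_error(decompose_gene(1:4, c("E1", "E1", "E2", "E2"),
                              c("A", "A", "A", "B")),
               "both lineages")
})

test_that("shuffling lineage labels within embryos leaves ss_embryo unchanged", {
  set.seed(1)
  d <- make_design(E = 4, n_per = 2)
  y <- rnorm(d$n)
  base <- decompose_gene(y, d$embryo, d$lineage)
  for (i in 1:5) {
    shuf <- unlist(tapply(d$lineage, d$embryo, sample), use.names = FALSE)
    expect_equal(decompose_gene(y, d$embryo, shuf)$ss_embryo, base$ss_embryo)
  }
})

test_that("sequential sums of squares match the aov oracle on random designs", {
  set.seed(7)
  for (i in 1:25) {
    E <- sample(2:5, 1); n_per <- sample(2:4, 1)
    d <- make_design(E, n_per)
    y <- rnorm(d$n, sd = runif(1, 0.5, 3))
    vp <- decompose_gene(y, d$embryo, d$lineage)
    fit <- stats::aov(y ~ factor(d$embryo) + factor(d$embryo):factor(d$lineage))
    ss <- summary(fit)[[1]][["Sum Sq"]]
    expect_equal(vp$ss_embryo, ss[1], tolerance = 1e-8)
    expect_equal(vp$ss_lineage, ss[2], tolerance = 1e-8)
    expect_equal(vp$ss_residual, ss[3], tolerance = 1e-8)
  }
})

test_that("the decomposition conserves the total sum of squares", {
  set.seed(8)
  cfg <- synthetic_config(seed = 8, n_genes = 200)
  sim <- simulate_cells_and_expression(cfg)
  cc <- sim$cells[sim$cells$stage == "four_cell", ]
  Y <- log2(sim$fpkm[, cc$cell_id] + 1)
  vp <- variance_partition_matrix(Y, cc$embryo_id, cc$lineage)
  total <- unname(rowSums((Y - rowMeans(Y))^2))
  expect_equal(vp$ss_embryo + vp$ss_lineage + vp$ss_residual, total,
               tolerance = 1e-8)
})

test_that("r is invariant to affine transforms of the response", {
  set.seed(9)
  d <- make_design(E = 3)
  y <- rnorm(d$n)
  r0 <- decompose_gene(y, d$embryo, d$lineage)$r
  expect_equal(decompose_gene(3.7 * y - 12, d$embryo, d$lineage)$r, r0)
  expect_equal(decompose_gene(-0.2 * y + 5, d$embryo, d$lineage)$r, r0)
})

test_that("null R has the Beta mean and planted genes rank high", {
  cfg <- synthetic_config(seed = 10, n_genes = 3000, frac_lineage_genes = 0,
                          n_embryos_8cell = 0, embryo_sd = 1e-9)
  sim <- simulate_cells_and_expression(cfg)
  r <- empirical_R(sim$fpkm, sim$cells, "four_cell")
  E <- cfg$n_embryos_4cell
  expect_lt(abs(mean(r) - E / (2 * E - 1)), 0.02)

  cfgp <- synthetic_config(seed = 10, n_genes = 1000, lineage_effect = 4)
  simp <- simulate_cells_and_expression(cfgp)
  rp <- empirical_R(simp$fpkm, simp$cells, "four_cell")
  planted <- simp$truth$gene_id[simp$truth$planted]
  null_median <- median(rp[setdiff(names(rp), planted)])
  expect_gt(mean(rp[planted] > null_median), 0.95)
})

test_that("empirical_R with no expressed genes is empty", {
  cells <- make_embryo_cells()
  cells2 <- make_embryo_cells("E2")
  all_cells <- validate_cells(rbind(cells, cells2))
  all_cells$lineage <- rep(c("A", "A", "B", "B"), 2)
  m <- matrix(0.5, 3, 8, dimnames = list(paste0("g", 1:3), all_cells$cell_id))
  expect_length(empirical_R(m, all_cells, "four_cell"), 0)
})

test_that("beta comparison: tails, KS distance and Q-Q monotonicity", {
  set.seed(11)
  u <- runif(20000)
  cmp <- compare_to_beta(u, params = list(c(1, 1)), deltas = c(0.05, 0.1, 0.2))[[1]]
  expect_equal(cmp$tails$analytic, c(0.05, 0.1, 0.2))
  expect_lt(max(abs(cmp$tails$empirical - cmp$tails$analytic)), 0.01)

  b <- rbeta(10000, 2, 2)
  cmp2 <- compare_to_beta(b, params = list(c(2, 2)))[[1]]
  expect_lt(cmp2$ks_distance, 0.02)
  expect_false(is.unsorted(cmp2$qq$beta_quantile))
  expect_false(is.unsorted(cmp2$qq$empirical_quantile))

  expect_error(compare_to_beta(numeric(0)), "empty")
})
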