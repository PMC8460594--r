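test_that("degenerate strong-law run reports the deterministic point", {
  rep1 <- run_slln_experiment("yhk", n_grid = 2, reps = 1, seed = 1)
  expect_equal(rep1$table$mean_A, 0)
  expect_equal(rep1$table$mean_B, 1 / 2)
  expect_true(all(unlist(rep1$pass)))
})

test_that("experiments are reproducible under a fixed seed", {
  a <- run_clt_experiment("yhk", n = 100, reps = 500, seed = 33)
  b <- run_clt_experiment("yhk", n = 100, reps = 500, seed = 33)
  expect_identical(a$table, b$table)
  expect_identical(a$mardia, b$mardia)

  s1 <- run_start_independence_experiment(
    "yhk", list(caterpillar_tree(8), caterpillar_tree(8)),
    n = 200, reps = 200, seed = 9)
  # identical starting trees, same seed stream: a valid, reproducible report
  expect_identical(s1$table$n_start, c(8L, 8L))
  s2 <- run_start_independence_experiment(
    "yhk", list(caterpillar_tree(8), caterpillar_tree(8)),
    n = 200, reps = 200, seed = 9)
  expect_identical(s1$table, s2$table)
})

test_that("analytic targets in reports come from the urn engine", {
  rp <- run_slln_experiment("pda", n_grid = c(100, 200), reps = 100, seed = 5)
  lim <- ab_limit_law("pda")$mean
  expect_equal(unique(rp$table$target_A), lim[1])
  expect_equal(unique(rp$table$target_B), lim[2])
  rc <- run_clt_experiment("pda", n = 100, reps = 500, seed = 6)
  expect_equal(rc$target_cov, ab_limit_law("pda")$Sigma)
})

test_that("moderate-size runs land within tolerance of the limit laws", {
  rs <- run_slln_experiment("yhk", n_grid = c(200, 800), reps = 400, seed = 71)
  expect_true(all(unlist(rs$pass)))
  # deviation from the limit shrinks along the grid
  dev <- abs(rs$table$mean_A - rs$table$target_A)
  expect_lt(dev[2], dev[1] + 3 * rs$table$se_A[1])

  rc <- run_clt_experiment("yhk", n = 500, reps = 1500, seed = 72)
  expect_true(all(unlist(rc$pass)))
  expect_true(all(is.finite(unlist(rc$mardia))))
  expect_gte(rc$mardia$kurtosis_p, 0)

  ri <- run_start_independence_experiment(
    "yhk", list(caterpillar_tree(8), balanced_tree(8)),
    n = 800, reps = 400, seed = 73)
  expect_true(all(abs(ri$pairwise$z_A) <= 3))
  expect_true(all(abs(ri$pairwise$z_B) <= 3))
})

test_that("Mardia diagnostics behave on a known bivariate normal sample", {
  set.seed(2)
  X <- matrix(rnorm(4000), ncol = 2)
  md <- treeurn:::mardia_stats(X)
  expect_gt(md$skewness_p, 1e-4)
  expect_gt(md$kurtosis_p, 1e-4)
})
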