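test_that("the forward recursion reproduces hand-enumerated small laws", {
  d3 <- evolve_distribution("yhk", n_target = 3)
  expect_equal(nrow(d3$states), 1)
  expect_identical(unname(d3$states[1, ]), c(2L, 0L, 1L, 0L))
  expect_identical(d3$prob_exact, "1")

  # two-step enumeration from the 2-leaf tree: 6 equally likely paths,
  # 4 reach (2,0,1,1) and 2 reach (0,4,0,0)
  d4 <- evolve_distribution("yhk", n_target = 4)
  key <- apply(d4$states, 1, paste, collapse = ",")
  expect_setequal(key, c("2,0,1,1", "0,4,0,0"))
  expect_identical(d4$prob_exact[key == "2,0,1,1"], "2/3")
  expect_identical(d4$prob_exact[key == "0,4,0,0"], "1/3")
  expect_equal(sum(d4$prob), 1)

  # all reachable states are non-negative (tenability)
  d10 <- evolve_distribution("pda", n_target = 10)
  expect_true(all(d10$states >= 0))
  expect_equal(sum(d10$prob), 1, tolerance = 1e-12)

  expect_error(evolve_distribution("pda", n_target = 26), "guard")
})

test_that("degenerate start: at n = 2 the law is a point mass with zero variance", {
  for (model in c("yhk", "pda")) {
    m <- exact_joint_moments(model, 2)
    expect_identical(unname(unlist(m$exact)), c("0", "1", "0", "0", "0"))
  }
})

test_that("DP moments equal the closed forms exactly (rational equality)", {
  for (n in 7:60) {
    dp <- exact_joint_moments("yhk", n)
    cf <- closed_form_moments("yhk", n)
    expect_identical(unlist(dp$exact), unlist(cf$exact), label = paste("yhk n =", n))
  }
  for (n in 7:20) {
    dp <- exact_joint_moments("pda", n)
    cf <- closed_form_moments("pda", n)
    expect_identical(unlist(dp$exact), unlist(cf$exact), label = paste("pda n =", n))
  }
  expect_error(closed_form_moments("yhk", 6), "n >= 7")
})

test_that("specific exact values hold at n = 20 and n = 7", {
  m <- exact_joint_moments("yhk", 20)
  expect_identical(m$exact$E_A, "10/3")     # n/6
  expect_identical(m$exact$V_A, "23/21")    # 23 n / 420
  expect_identical(exact_joint_moments("yhk", 7)$exact$Cov_AB, "-7/45")
  # PDA at n = 7, confirmed by exhaustive 10395-path enumeration:
  m7 <- exact_joint_moments("pda", 7)
  expect_identical(m7$exact$E_B, "21/11")
  expect_identical(m7$exact$V_B, "140/363")
})

test_that("moments from an arbitrary start approach the same limits at rate O(1/n)", {
  tr <- exact_moment_trajectory("yhk", 150, start_tree = caterpillar_tree(8))
  err <- abs(tr$E_A / tr$n - 1 / 6)
  e20 <- err[tr$n == 20]; e150 <- err[tr$n == 150]
  expect_lt(e150, e20) # shrinking
  expect_lt(e150, 2 * e20 * 20 / 150) # O(1/n) with modest slack
  # variance rate approaches the CLT diagonal
  vlim <- ab_limit_law("yhk")$Sigma[1, 1]
  expect_equal(tr$V_A[tr$n == 150] / 150, vlim, tolerance = 0.05)
})

test_that("unrooted six-leaf shape atoms carry probabilities 4/5 and 1/5", {
  d <- exact_unrooted_shape_dist("yhk", 6)
  expect_equal(nrow(d), 2)
  expect_identical(unname(unlist(d[d$E1 == 4, c("prob_exact")])), "4/5")
  expect_identical(unname(unlist(d[d$E1 == 0, c("prob_exact")])), "1/5")
  expect_identical(unname(as.integer(as.matrix(d[d$E1 == 4, 1:4]))), c(4L, 0L, 2L, 0L))
  expect_identical(unname(as.integer(as.matrix(d[d$E1 == 0, 1:4]))), c(0L, 6L, 0L, 0L))
  expect_equal(sum(d$prob), 1)

  # simulated unrooted trajectories agree within Monte-Carlo error
  reps <- 2000
  set.seed(17)
  hits <- sum(replicate(reps, alpha_vector(grow("yhk", 6, rooted = FALSE))[1] == 4))
  se <- sqrt(0.8 * 0.2 / reps)
  expect_lt(abs(hits / reps - 0.8), 3 * se)

  expect_error(exact_unrooted_shape_dist("yhk", 5), "6 <= n")
})

test_that("PDA unrooted enumeration at n = 6 sums to one over both atoms", {
  d <- exact_unrooted_shape_dist("pda", 6)
  expect_equal(nrow(d), 2)
  expect_equal(sum(d$prob), 1)
  expect_setequal(apply(d[, 1:4], 1, paste, collapse = ","),
                  c("4,0,2,0", "0,6,0,0"))
})
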