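test_that("growth is reproducible and single steps behave as expected", {
  a <- grow("yhk", 40, seed = 11)
  b <- grow("yhk", 40, seed = 11)
  expect_identical(write_newick(a), write_newick(b))
  c <- grow("pda", 40, seed = 11)
  expect_false(identical(write_newick(a), write_newick(c)))

  # from the 2-leaf tree every YHK step gives the 3-leaf pitchfork
  set.seed(1)
  for (i in 1:5) {
    t3 <- yhk_step(two_leaf_tree())
    expect_identical(unname(count_ab(t3)), c(1L, 1L))
  }
  # pda_step adds one leaf and two edges
  t5 <- tree_t5()
  s <- pda_step(t5)
  expect_equal(n_leaves(s), 6)
  expect_equal(length(s$parent) - length(t5$parent), 2)
})

test_that("attaching to an edge of each type shifts the census by the matrix row", {
  Ry <- yhk_replacement_matrix()
  Rp <- pda_replacement_matrix()
  fixtures <- list(two_leaf_tree(), parse_newick("((1,2),3);"), tree_t5(),
                   tree_three_cherries(), caterpillar_tree(6), balanced_tree(8),
                   grow("yhk", 12, seed = 2), grow("pda", 12, seed = 3))
  seen <- integer(0)
  for (tr in fixtures) {
    b0 <- beta_vector(tr)
    a0 <- alpha_vector(tr)
    ed <- enumerate_edges(tr)
    for (k in seq_len(nrow(ed))) {
      ty <- classify_edge(tr, ed$edge[k])
      seen <- union(seen, ty)
      grown <- attach_leaf(tr, ed$edge[k])
      expect_identical(unname(beta_vector(grown) - b0), Rp[ty, ])
      if (ed$pendant[k])
        expect_identical(unname(alpha_vector(grown) - a0), Ry[ty, ])
    }
  }
  expect_setequal(seen, 1:6) # every edge type was exercised
})

test_that("recorded trajectories satisfy the urn recursion and conservation laws", {
  tr <- grow("yhk", 6, seed = 9, record_trajectory = TRUE)
  traj <- attr(tr, "trajectory")
  types <- attr(tr, "step_types")
  expect_equal(unname(rowSums(traj)), 2:6)          # sum(alpha) = leaves
  Ry <- yhk_replacement_matrix()
  for (k in seq_along(types))
    expect_identical(unname(traj[k + 1, ] - traj[k, ]), Ry[types[k], ])

  tp <- grow("pda", 7, seed = 9, record_trajectory = TRUE)
  trajp <- attr(tp, "trajectory")
  typesp <- attr(tp, "step_types")
  expect_equal(unname(rowSums(trajp)), 2 * (2:7) - 1) # sum(beta) = 2n - 1
  Rp <- pda_replacement_matrix()
  for (k in seq_along(typesp))
    expect_identical(unname(trajp[k + 1, ] - trajp[k, ]), Rp[typesp[k], ])
})

test_that("sample_joint matches exact small-n laws", {
  ab <- sample_joint("yhk", 2, 20, seed = 4)
  expect_true(all(ab$A == 0 & ab$B == 1))

  # P(pitchfork shape at n = 4) = 2/3 under YHK (4 of the 6 equally
  # likely two-step growth paths from the 2-leaf tree)
  reps <- 3000
  ab4 <- sample_joint("yhk", 4, reps, seed = 8)
  phat <- mean(ab4$A == 1)
  se <- sqrt(2 / 3 * 1 / 3 / reps)
  expect_lt(abs(phat - 2 / 3), 3 * se)
})

test_that("empirical per-leaf means approach the analytic limits from any start", {
  reps <- 800; n <- 1500
  lim <- ab_limit_law("yhk")$mean
  for (start in list(NULL, caterpillar_tree(8))) {
    ab <- sample_joint("yhk", n, reps, seed = 21, start_tree = start)
    m <- mean(ab$A / n); se <- sd(ab$A / n) / sqrt(reps)
    expect_lt(abs(m - lim[1]), 3 * se + 1e-12)
  }
  limp <- ab_limit_law("pda")$mean
  abp <- sample_joint("pda", n, reps, seed = 22)
  expect_lt(abs(mean(abp$B / n) - limp[2]), 3 * sd(abp$B / n) / sqrt(reps))
})

test_that("unrooted growth keeps unrooted invariants", {
  tr <- grow("yhk", 25, rooted = FALSE, seed = 13)
  expect_false(tr$rooted)
  expect_equal(length(tr$parent) - 1L, 2 * 25 - 3)
  expect_equal(sum(beta_vector(tr)), 2 * 25 - 3)
  trp <- grow("pda", 25, rooted = FALSE, seed = 13)
  expect_equal(sum(enumerate_edges(trp)$pendant), 25)
})
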