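test_that("worked-example censuses are reproduced", {
  t2 <- two_leaf_tree()
  expect_identical(unname(alpha_vector(t2)), c(0L, 2L, 0L, 0L))
  expect_identical(unname(beta_vector(t2)), c(0L, 2L, 0L, 0L, 1L, 0L))
  ed <- enumerate_edges(t2)
  expect_true(all(classify_edge(t2, ed$edge[ed$pendant]) == 2L))
  expect_equal(classify_edge(t2, ed$edge[!ed$pendant]), 5L) # root edge

  p3 <- parse_newick("((1,2),3);")
  expect_identical(unname(alpha_vector(p3)), c(2L, 0L, 1L, 0L))
  e3 <- enumerate_edges(p3)
  lone <- e3$edge[!is.na(e3$label) & e3$label == "3"]
  expect_equal(classify_edge(p3, lone), 3L)

  t5 <- tree_t5()
  expect_identical(unname(alpha_vector(t5)), c(2L, 2L, 1L, 0L))
  expect_identical(unname(beta_vector(t5)), c(2L, 2L, 1L, 0L, 1L, 3L))

  expect_identical(unname(alpha_vector(tree_three_cherries())),
                   c(0L, 6L, 0L, 0L))
})

test_that("three independent cherries give three type-5 internal edges", {
  # each independent cherry contributes exactly one adjacent internal edge,
  # so beta_5 = beta_2 / 2 forces (0,6,0,0,3,2) for the rooted tree
  expect_identical(unname(beta_vector(tree_three_cherries())),
                   c(0L, 6L, 0L, 0L, 3L, 2L))
  # and (0,6,0,0,3,0) for its unrooted version (3 internal edges in total)
  expect_identical(unname(beta_vector(unroot(tree_three_cherries()))),
                   c(0L, 6L, 0L, 0L, 3L, 0L))
})

test_that("typing refuses unrooted trees below six leaves", {
  u5 <- parse_newick("((1,2),(3,4),5);", rooted = FALSE)
  expect_error(alpha_vector(u5), "at least 6")
  expect_error(count_pitchforks(u5), "at least 6")
  expect_equal(count_cherries(u5), 2)
})

test_that("subtree census and edge-type census agree on random trees", {
  t2fig <- attach_leaf(tree_fig1_t1(), pendant_edge_of(tree_fig1_t1(), "1"), "8")
  expect_equal(count_pitchforks(t2fig), 1)
  expect_equal(count_cherries(t2fig), 3)

  expect_identical(unname(count_ab(two_leaf_tree())), c(0L, 1L))

  set.seed(42)
  for (model in c("yhk", "pda")) {
    for (i in 1:60) {
      n <- sample(8:60, 1)
      tr <- grow(model, n)
      a <- alpha_vector(tr); b <- beta_vector(tr)
      A <- count_pitchforks(tr); B <- count_cherries(tr)
      expect_identical(unname(a), unname(b[1:4]))
      expect_equal(sum(a), n)              # one pendant edge per leaf
      expect_equal(sum(b), 2 * n - 1)      # partition of the edge set
      expect_equal(A, a[[1]] / 2)          # pitchforks = type-1 edges / 2
      expect_equal(B - A, a[[2]] / 2)      # independent cherries = type-2 / 2
      expect_equal(a[[3]], a[[1]] / 2)     # one type-3 edge per pitchfork
      expect_equal(b[[5]], b[[2]] / 2)     # one type-5 edge per indep. cherry
      expect_identical(unname(count_ab(tr)), c(A, B))
      # unrooted version stays coherent
      u <- unroot(tr)
      bu <- beta_vector(u)
      expect_equal(sum(bu), 2 * n - 3)
      expect_equal(bu[[5]], bu[[2]] / 2)
      expect_equal(count_pitchforks(u), bu[[1]] / 2)
      expect_equal(count_cherries(u) - count_pitchforks(u), bu[[2]] / 2)
      expect_identical(unname(count_ab(u)),
                       c(count_pitchforks(u), count_cherries(u)))
    }
  }
})
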