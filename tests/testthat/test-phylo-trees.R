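test_that("Newick parsing builds validated trees with the right edge counts", {
  t3 <- parse_newick("((1,2),3);")
  expect_equal(n_leaves(t3), 3)
  expect_equal(length(t3$parent) - 1L, 5) # 2n - 1 edges

  t2 <- parse_newick("(1,2);")
  expect_equal(n_leaves(t2), 2)
  expect_equal(length(t2$parent) - 1L, 3)

  u5 <- parse_newick("((1,2),(3,4),5);", rooted = FALSE)
  expect_equal(n_leaves(u5), 5)
  expect_equal(length(u5$parent) - 1L, 7) # 2n - 3 edges

  # branch lengths are accepted and dropped
  tb <- parse_newick("((1:0.1,2:0.2):0.3,3:0.4);")
  expect_equal(n_leaves(tb), 3)

  expect_error(parse_newick("((1,2,3),4);"), "non-binary")
  expect_error(parse_newick("((1,2"), "malformed")
})

test_that("Newick round trip preserves topology, labels and type censuses", {
  for (txt in c("((1,2),3);", "(((a,b),c),(d,e));", "((a,b),((c,d),(e,f)));")) {
    tr <- parse_newick(txt)
    tr2 <- parse_newick(write_newick(tr))
    expect_isomorphic(tr, tr2)
    expect_identical(beta_vector(tr), beta_vector(tr2))
  }
  u <- parse_newick("((1,2),(3,4),(5,6));", rooted = FALSE)
  u2 <- parse_newick(write_newick(u), rooted = FALSE)
  expect_isomorphic(u, u2)
  expect_identical(beta_vector(u), beta_vector(u2))
})

test_that("attach_leaf implements the edge-subdivision move", {
  # worked 8-leaf example: leaf 8 on the pendant edge of taxon 1
  t1 <- tree_fig1_t1()
  t2 <- attach_leaf(t1, pendant_edge_of(t1, "1"), "8")
  expect_equal(n_leaves(t2), 8)
  expect_identical(unname(count_ab(t2)), c(1L, 3L))
  expect_equal(length(t2$parent) - length(t1$parent), 2) # two new edges
  # it survives a Newick round trip
  t2rt <- parse_newick(write_newick(t2))
  expect_identical(unname(count_ab(t2rt)), c(1L, 3L))

  # any pendant attachment on the 2-leaf tree gives the 3-leaf pitchfork
  t <- two_leaf_tree()
  for (e in enumerate_edges(t)$edge[enumerate_edges(t)$pendant]) {
    t3 <- attach_leaf(t, e)
    expect_identical(unname(count_ab(t3)), c(1L, 1L))
  }

  # every edge of every tree gains exactly 2 edges when subdivided
  tr <- tree_t5()
  for (e in enumerate_edges(tr)$edge)
    expect_equal(length(attach_leaf(tr, e)$parent) - length(tr$parent), 2)

  expect_error(attach_leaf(t, 99), "unknown edge")
  expect_error(attach_leaf(t, enumerate_edges(t)$edge[1], "1"), "duplicate")
})

test_that("edge enumeration is deterministic with the right pendant census", {
  t <- two_leaf_tree()
  ed <- enumerate_edges(t)
  expect_equal(nrow(ed), 3)
  expect_equal(sum(ed$pendant), 2)

  tr <- grow("yhk", 20, seed = 5)
  e1 <- enumerate_edges(tr); e2 <- enumerate_edges(tr)
  expect_identical(e1, e2)
  expect_equal(sum(e1$pendant), 20)       # n pendant edges
  expect_equal(nrow(e1), 39)              # 2n - 1 edges

  ur <- unroot(tr)
  eu <- enumerate_edges(ur)
  expect_equal(nrow(eu), 37)              # 2n - 3 edges
  expect_equal(sum(eu$pendant), 20)
})

test_that("unrooting removes rho, suppresses its child, and keeps censuses coherent", {
  p3 <- parse_newick("((1,2),3);")
  u3 <- unroot(p3)
  expect_equal(length(u3$parent) - 1L, 3)

  expect_error(unroot(two_leaf_tree()), "at least 3 leaves")

  u6 <- unroot(tree_three_cherries())
  expect_identical(unname(alpha_vector(u6)), c(0L, 6L, 0L, 0L))

  # attach-then-unroot agrees with unroot-then-attach on a pendant edge
  tr <- tree_three_cherries()
  a <- unroot(attach_leaf(tr, pendant_edge_of(tr, "c"), "x"))
  ur <- unroot(tr)
  b <- attach_leaf(ur, pendant_edge_of(ur, "c"), "x")
  expect_isomorphic(a, b)
})
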