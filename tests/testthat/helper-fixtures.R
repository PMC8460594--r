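# Worked-example trees used throughout the suite (built in code, no files).

# 5-leaf tree with one pitchfork and one independent cherry:
# beta = (2, 2, 1, 0, 1, 3)
tree_t5 <- function() parse_newick("(((a,b),c),(d,e));")

# rooted 6-leaf tree consisting of three independent cherries
tree_three_cherries <- function() parse_newick("((a,b),((c,d),(e,f)));")

# 7-leaf tree whose pendant edge at taxon 1, once a leaf "8" is attached,
# yields an 8-leaf tree with A = 1 pitchfork and B = 3 cherries
tree_fig1_t1 <- function() parse_newick("(((1,2),3),((4,5),(6,7)));")

pendant_edge_of <- function(tree, label) {
  ed <- enumerate_edges(tree)
  ed$edge[!is.na(ed$label) & ed$label == label]
}

# label-respecting isomorphism via Robinson-Foulds distance (n >= 4);
# small trees are compared by census + label set
expect_isomorphic <- function(a, b) {
  expect_setequal(a$labels[!is.na(a$labels)], b$labels[!is.na(b$labels)])
  expect_identical(a$rooted, b$rooted)
  if (a$rooted) {
    expect_true(isTRUE(ape::all.equal.phylo(treeurn:::to_phylo(a),
                                            treeurn:::to_phylo(b),
                                            use.edge.length = FALSE)))
  } else if (a$nleaf >= 4L) {
    d <- ape::dist.topo(treeurn:::to_phylo(a), treeurn:::to_phylo(b))
    expect_equal(unname(as.numeric(d)), 0)
  } else {
    expect_identical(count_ab(a), count_ab(b))
  }
}

# chi-square goodness of fit of sampled edge-type states against exact DP
# probabilities, pooling states with small expected counts
gof_pvalue <- function(sampled_keys, dp) {
  keys <- apply(dp$states, 1, paste, collapse = ",")
  expect_true(all(sampled_keys %in% keys))
  obs <- table(factor(sampled_keys, levels = keys))
  m <- length(sampled_keys)
  expc <- dp$prob * m
  pool <- expc < 10
  if (any(pool) && sum(pool) > 1) {
    obs <- c(obs[!pool], other = sum(obs[pool]))
    expc <- c(expc[!pool], sum(expc[pool]))
  }
  chi <- sum((obs - expc)^2 / expc)
  stats::pchisq(chi, df = length(expc) - 1L, lower.tail = FALSE)
}
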