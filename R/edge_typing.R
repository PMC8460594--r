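# Edge types 1-6.
#
# Pendant edges: type 1 lies in a dependent cherry (a cherry inside a
# pitchfork), type 2 in an independent cherry, type 3 in a pitchfork but
# not a cherry, type 4 in neither.  Internal edges: type 5 is adjacent to
# an independent cherry (its child-side subtree is exactly that cherry),
# type 6 is any other internal edge.  The six sets partition the edge set;
# for rooted trees the root edge (rho, child) is internal and eligible for
# type 5.  Unrooted typing is well defined only for n >= 6.

check_typing_size <- function(tree) {
  if (!tree$rooted && tree$nleaf < 6L)
    stop("edge typing on unrooted trees requires at least 6 leaves ",
         "(smaller trees admit no consistent type assignment)")
  if (tree$rooted && tree$nleaf < 2L) stop("tree too small for edge typing")
}

#' Classify one edge into types 1-6
#'
#' @param tree an `urn_tree` (rooted with >= 2 leaves, or unrooted with
#'   >= 6 leaves).
#' @param edge edge id (child-vertex id, see [enumerate_edges()]).
#' @return integer in 1..6.
#' @export
classify_edge <- function(tree, edge) {
  check_typing_size(tree)
  edge <- as.integer(edge)
  nv <- length(tree$parent)
  if (any(is.na(edge)) || any(edge < 2L) || any(edge > nv))
    stop("unknown edge id")
  types <- classify_edges_cpp(tree$parent, tree$lchild, tree$rchild,
                              tree$rooted, tree$nleaf)
  types[edge]
}

edge_types <- function(tree) {
  check_typing_size(tree)
  types <- classify_edges_cpp(tree$parent, tree$lchild, tree$rchild,
                              tree$rooted, tree$nleaf)
  types[-1L]
}

#' Pendant edge-type census (the 4-entry alpha vector)
#'
#' Counts of pendant edge types 1-4; the entries sum to the number of
#' leaves.  The pitchfork count is `alpha[1] / 2` and the cherry count is
#' `(alpha[1] + alpha[2]) / 2`.
#'
#' @inheritParams classify_edge
#' @return named integer vector of length 4.
#' @export
alpha_vector <- function(tree) {
  tt <- edge_types(tree)
  out <- tabulate(tt[tt <= 4L], nbins = 4L)
  names(out) <- paste0("E", 1:4)
  out
}

#' Full edge-type census (the 6-entry beta vector)
#'
#' Counts of edge types 1-6; the first four entries equal
#' [alpha_vector()], and the entries sum to the edge count (2n - 1 rooted,
#' 2n - 3 unrooted).
#'
#' @inheritParams classify_edge
#' @return named integer vector of length 6.
#' @export
beta_vector <- function(tree) {
  tt <- edge_types(tree)
  out <- tabulate(tt, nbins = 6L)
  names(out) <- paste0("E", 1:6)
  out
}

# Independent subtree census (used to cross-check the edge-type route):
# subtree leaf counts by postorder accumulation, then count subtrees with
# exactly 2 or 3 leaves on the small side of an edge.
subtree_census <- function(tree) {
  nv <- length(tree$parent)
  cnt <- integer(nv)
  cnt[!is.na(tree$labels)] <- 1L
  for (v in rev(preorder_vertices(tree))) {
    kids <- c(tree$lchild[v], tree$rchild[v])
    kids <- kids[kids != 0L]
    if (length(kids)) cnt[v] <- cnt[v] + sum(cnt[kids])
  }
  cnt
}

#' Count cherries
#'
#' A cherry is a two-leaf subtree: for rooted trees a vertex with exactly
#' two descendant leaves; for unrooted trees (n >= 4) a two-leaf component
#' cut off by a single edge.
#'
#' @param tree an `urn_tree` (rooted n >= 2, unrooted n >= 4).
#' @return integer.
#' @export
count_cherries <- function(tree) {
  if (!tree$rooted && tree$nleaf < 4L)
    stop("cherry counting on unrooted trees requires at least 4 leaves")
  cnt <- subtree_census(tree)
  n <- tree$nleaf
  if (tree$rooted) sum(cnt[-1L] == 2L)
  else sum(cnt[-1L] == 2L) + sum((n - cnt[-1L]) == 2L)
}

#' Count pitchforks
#'
#' A pitchfork is a three-leaf subtree: for rooted trees a vertex with
#' exactly three descendant leaves; for unrooted trees (n >= 6) a
#' three-leaf component cut off by a single edge.
#'
#' @param tree an `urn_tree` (rooted n >= 2, unrooted n >= 6).
#' @return integer.
#' @export
count_pitchforks <- function(tree) {
  if (!tree$rooted && tree$nleaf < 6L)
    stop("pitchfork counting on unrooted trees requires at least 6 leaves")
  cnt <- subtree_census(tree)
  n <- tree$nleaf
  if (tree$rooted) sum(cnt[-1L] == 3L)
  else sum(cnt[-1L] == 3L) + sum((n - cnt[-1L]) == 3L)
}

#' Joint cherry and pitchfork counts
#'
#' Fast C++ census of (A, B) = (pitchforks, cherries) used by the growth
#' simulators; agrees with [count_pitchforks()] / [count_cherries()].
#'
#' @param tree an `urn_tree`.
#' @return named integer vector `c(A = ..., B = ...)`.
#' @export
count_ab <- function(tree) {
  count_ab_cpp(tree$parent, tree$lchild, tree$rchild, tree$rooted, tree$nleaf)
}
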