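# YHK and PDA growth processes.
#
# One step attaches a new leaf to a uniformly chosen pendant edge (YHK) or
# to a uniformly chosen edge, pendant or internal (PDA).  Both processes
# run on rooted trees (where the root edge below rho counts among the
# 2n - 1 candidate edges of the PDA step) and on unrooted trees.  The fast
# path is compiled; `yhk_step()` / `pda_step()` are an independent pure-R
# route over `enumerate_edges()` + `attach_leaf()` used for cross-checks.

#' One YHK growth step
#'
#' Attaches a new leaf to a uniformly chosen pendant edge, using the
#' canonical edge order of [enumerate_edges()] and the R RNG stream.
#'
#' @param tree an `urn_tree`.
#' @param label optional label for the new leaf.
#' @return the enlarged tree.
#' @export
yhk_step <- function(tree, label = NULL) {
  ed <- enumerate_edges(tree)
  pend <- ed$edge[ed$pendant]
  attach_leaf(tree, pend[sample.int(length(pend), 1L)], label)
}

#' One PDA growth step
#'
#' Attaches a new leaf to a uniformly chosen edge (pendant or internal;
#' for rooted trees this includes the root edge, giving 2n - 1 candidates).
#'
#' @inheritParams yhk_step
#' @return the enlarged tree.
#' @export
pda_step <- function(tree, label = NULL) {
  ed <- enumerate_edges(tree)
  attach_leaf(tree, ed$edge[sample.int(nrow(ed), 1L)], label)
}

model_code <- function(model) {
  model <- match.arg(tolower(model), c("yhk", "pda"))
  c(yhk = 0L, pda = 1L)[[model]]
}

#' Grow a random tree
#'
#' Runs the YHK or PDA process from a starting tree (default: the two-leaf
#' tree) up to `n_target` leaves.  Identical seeds reproduce identical
#' trees.  When `record_trajectory = TRUE` the growth runs step by step in
#' R and the edge-type census (alpha for YHK, beta for PDA) is re-measured
#' on the tree after every step, so the recorded trajectory is an
#' independent observation of the urn recursion, not a replay of it.
#'
#' @param model `"yhk"` or `"pda"`.
#' @param n_target number of leaves to grow to.
#' @param start_tree starting `urn_tree`; default two-leaf tree of the
#'   requested rootedness.
#' @param rooted used only when `start_tree` is NULL.
#' @param seed optional RNG seed.
#' @param record_trajectory record the per-step edge-type census.
#' @return an `urn_tree`; with `record_trajectory`, attributes
#'   `"trajectory"` (matrix of censuses, one row per size) and
#'   `"step_types"` (type of the edge chosen at each step).
#' @export
grow <- function(model = c("yhk", "pda"), n_target, start_tree = NULL,
                 rooted = TRUE, seed = NULL, record_trajectory = FALSE) {
  model <- match.arg(model)
  if (is.null(start_tree)) start_tree <- two_leaf_tree(rooted = rooted)
  validate_urn_tree(start_tree)
  if (n_target < start_tree$nleaf)
    stop("n_target (", n_target, ") is smaller than the starting tree (",
         start_tree$nleaf, " leaves)")
  if (!is.null(seed)) set.seed(seed)

  if (record_trajectory) {
    census <- function(tr) {
      typed <- tr$rooted || tr$nleaf >= 6L
      if (!typed) return(rep(NA_integer_, if (model == "yhk") 4L else 6L))
      if (model == "yhk") alpha_vector(tr) else beta_vector(tr)
    }
    steps <- n_target - start_tree$nleaf
    tr <- start_tree
    traj <- matrix(NA_integer_, steps + 1L, if (model == "yhk") 4L else 6L)
    types <- integer(steps)
    traj[1L, ] <- census(tr)
    for (k in seq_len(steps)) {
      ed <- enumerate_edges(tr)
      cand <- if (model == "yhk") ed$edge[ed$pendant] else ed$edge
      e <- cand[sample.int(length(cand), 1L)]
      typed <- tr$rooted || tr$nleaf >= 6L
      types[k] <- if (typed) classify_edge(tr, e) else NA_integer_
      tr <- attach_leaf(tr, e)
      traj[k + 1L, ] <- census(tr)
    }
    rownames(traj) <- as.character(seq(start_tree$nleaf, n_target))
    colnames(traj) <- paste0("E", seq_len(ncol(traj)))
    attr(tr, "trajectory") <- traj
    attr(tr, "step_types") <- types
    return(tr)
  }

  res <- grow_cpp(start_tree$parent, start_tree$lchild, start_tree$rchild,
                  start_tree$rooted, start_tree$nleaf,
                  model_code(model), n_target, FALSE)
  nv0 <- length(start_tree$parent)
  nv1 <- length(res$parent)
  labels <- c(start_tree$labels, rep(NA_character_, nv1 - nv0))
  newleaves <- seq(nv0 + 2L, nv1, by = 2L)
  if (nv1 > nv0) labels[newleaves] <- default_new_labels(start_tree, length(newleaves))
  new_urn_tree(res$parent, res$lchild, res$rchild, labels, start_tree$rooted)
}

#' Sample replicate (pitchfork, cherry) counts
#'
#' Grows `reps` independent trees to `n` leaves under the chosen model and
#' returns the joint subtree counts, the raw material for the strong-law
#' and CLT experiments.
#'
#' @param model `"yhk"` or `"pda"`.
#' @param n leaves per tree.
#' @param reps number of replicate trees.
#' @param seed optional RNG seed.
#' @param start_tree starting tree (default: two-leaf tree).
#' @param rooted used only when `start_tree` is NULL.
#' @return a data frame with columns `replicate`, `A` (pitchforks), `B`
#'   (cherries).
#' @export
sample_joint <- function(model = c("yhk", "pda"), n, reps, seed = NULL,
                         start_tree = NULL, rooted = TRUE) {
  model <- match.arg(model)
  if (is.null(start_tree)) start_tree <- two_leaf_tree(rooted = rooted)
  validate_urn_tree(start_tree)
  if (n < start_tree$nleaf) stop("n is smaller than the starting tree")
  if (reps < 1) stop("reps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  ab <- sample_joint_cpp(start_tree$parent, start_tree$lchild,
                         start_tree$rchild, start_tree$rooted,
                         start_tree$nleaf, model_code(model), n, reps)
  data.frame(replicate = seq_len(reps), A = ab[, 1L], B = ab[, 2L])
}

#' Convenience: one random tree
#'
#' @inheritParams sample_joint
#' @return an `urn_tree` with `n` leaves.
#' @export
random_tree <- function(model = c("yhk", "pda"), n, rooted = TRUE, seed = NULL,
                        start_tree = NULL) {
  grow(model, n, start_tree = start_tree, rooted = rooted, seed = seed)
}

# Shape builders used in examples and experiments -------------------------

#' Caterpillar (fully unbalanced) rooted tree
#' @param n number of leaves (>= 2).
#' @return a rooted `urn_tree`.
#' @export
caterpillar_tree <- function(n) {
  stopifnot(n >= 2)
  txt <- "(1,2)"
  for (k in seq_len(n - 2) + 2) txt <- sprintf("(%s,%d)", txt, k)
  parse_newick(paste0(txt, ";"), rooted = TRUE)
}

#' Fully balanced rooted tree
#' @param n number of leaves (a power of two).
#' @return a rooted `urn_tree`.
#' @export
balanced_tree <- function(n) {
  stopifnot(n >= 2, bitwAnd(n, n - 1L) == 0L)
  build <- function(lo, hi) {
    if (lo == hi) return(as.character(lo))
    mid <- (lo + hi) %/% 2L
    sprintf("(%s,%s)", build(lo, mid), build(mid + 1L, hi))
  }
  parse_newick(paste0(build(1L, as.integer(n)), ";"), rooted = TRUE)
}
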