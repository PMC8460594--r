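# Exact finite-n law of (A_n, B_n).
#
# The transition law of either growth process depends on the tree only
# through its edge-type census, so the census is a Markov chain on a
# polynomial-sized state space (instead of the Catalan-sized shape space).
# The forward recursion is carried out in exact rational arithmetic: from a
# state C, colour i is selected with probability C_i / t and the state
# moves to C + R[i, ].  All probabilities at a given step share the
# denominator prod t_k, so the compiled DP only needs big-integer
# numerators.

dp_guard_default <- c(yhk = 200L, pda = 25L)

start_state_for <- function(model, start_tree = NULL) {
  if (is.null(start_tree)) start_tree <- two_leaf_tree(rooted = TRUE)
  if (model == "yhk") alpha_vector(start_tree) else beta_vector(start_tree)
}

state_leaf_count <- function(model, state, rooted = TRUE) {
  # alpha sums to n; beta sums to 2n - 1 (rooted) or 2n - 3 (unrooted)
  if (model == "yhk") sum(state)
  else (sum(state) + if (rooted) 1 else 3) / 2
}

#' Exact distribution of the edge-type census at n leaves
#'
#' Runs the exact rational forward recursion of the edge-type Markov chain
#' from a starting census to `n_target` leaves.
#'
#' @param model `"yhk"` or `"pda"`.
#' @param start_state integer edge-type census (length 4 for YHK, 6 for
#'   PDA); default: the census of the two-leaf rooted tree.
#' @param n_target leaf count to evolve to.
#' @param guard state-space guard: maximal `n_target` (default 200 for
#'   YHK, 25 for PDA); raise explicitly for larger exact runs.
#' @param rooted whether the census describes a rooted tree (affects the
#'   leaf count implied by a PDA census: the edge total is 2n - 1 rooted,
#'   2n - 3 unrooted).
#' @return a list of class `state_distribution`: `n`, `states` (matrix,
#'   one row per reachable census), `prob` (numeric), `prob_exact`
#'   (reduced `"p/q"` strings).
#' @export
evolve_distribution <- function(model = c("yhk", "pda"), start_state = NULL,
                                n_target, guard = NULL, rooted = TRUE) {
  model <- match.arg(model)
  if (is.null(start_state)) start_state <- start_state_for(model)
  d <- if (model == "yhk") 4L else 6L
  if (length(start_state) != d)
    stop("start_state must have length ", d, " for the ", toupper(model), " urn")
  if (is.null(guard)) guard <- dp_guard_default[[model]]
  if (n_target > guard)
    stop("n_target = ", n_target, " exceeds the state-space guard (", guard,
         "); pass `guard =` explicitly to override")
  n0 <- state_leaf_count(model, start_state, rooted)
  if (n_target < n0) stop("n_target is smaller than the starting census size")
  R <- if (model == "yhk") yhk_replacement_matrix() else pda_replacement_matrix()
  res <- dp_evolve_cpp(as.integer(start_state), R, as.integer(n_target - n0),
                       TRUE, FALSE)
  structure(list(model = model, n = n_target, states = res$states,
                 prob = res$prob, prob_exact = res$prob_exact,
                 moments = res$moments, moments_exact = res$moments_exact),
            class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  cat(sprintf("exact %s edge-type distribution at n = %d (%d states)\n",
              toupper(x$model), x$n, nrow(x$states)))
  show <- order(x$prob, decreasing = TRUE)[seq_len(min(6L, nrow(x$states)))]
  for (i in show)
    cat(sprintf("  (%s): %s\n", paste(x$states[i, ], collapse = ","),
                x$prob_exact[i]))
  invisible(x)
}

parse_exact <- function(s) {
  # "p/q" or "p" -> c(num, den) as exact doubles; stops beyond 2^53
  parts <- strsplit(s, "/", fixed = TRUE)[[1]]
  num <- as.numeric(parts[1])
  den <- if (length(parts) == 2L) as.numeric(parts[2]) else 1
  if (abs(num) > .Q_MAX || den > .Q_MAX)
    stop("exact value does not fit a double: ", s)
  c(num, den)
}

moment_table <- function(model, n, exact, numeric, source) {
  structure(list(model = model, n = n, E_A = numeric[["E_A"]],
                 E_B = numeric[["E_B"]], V_A = numeric[["V_A"]],
                 V_B = numeric[["V_B"]], Cov_AB = numeric[["Cov_AB"]],
                 exact = exact, source = source),
            class = "moment_table")
}

#' @export
print.moment_table <- function(x, ...) {
  cat(sprintf("%s moments of (A_n, B_n) at n = %d [%s]\n", toupper(x$model),
              x$n, x$source))
  for (k in c("E_A", "E_B", "V_A", "V_B", "Cov_AB"))
    cat(sprintf("  %-6s = %-14s (%.8g)\n", k, x$exact[[k]], x[[k]]))
  invisible(x)
}

#' Exact joint moments of (A_n, B_n) by dynamic programming
#'
#' Mean, variance and covariance of the pitchfork and cherry counts at `n`
#' leaves, computed exactly from the DP distribution (A = alpha1/2,
#' B = (alpha1 + alpha2)/2).
#'
#' @inheritParams evolve_distribution
#' @param n leaf count.
#' @param start_tree optional starting tree (default: two-leaf rooted).
#' @return a `moment_table`: numeric fields `E_A`, `E_B`, `V_A`, `V_B`,
#'   `Cov_AB` plus `exact`, a named character vector of reduced rationals.
#' @export
exact_joint_moments <- function(model = c("yhk", "pda"), n, start_tree = NULL,
                                guard = NULL) {
  model <- match.arg(model)
  start_state <- start_state_for(model, start_tree)
  rooted <- if (is.null(start_tree)) TRUE else start_tree$rooted
  if (is.null(guard)) guard <- dp_guard_default[[model]]
  if (n > guard)
    stop("n = ", n, " exceeds the state-space guard (", guard,
         "); pass `guard =` explicitly to override")
  n0 <- state_leaf_count(model, start_state, rooted)
  if (n < n0) stop("n is smaller than the starting tree")
  R <- if (model == "yhk") yhk_replacement_matrix() else pda_replacement_matrix()
  res <- dp_evolve_cpp(as.integer(start_state), R, as.integer(n - n0),
                       FALSE, FALSE)
  moment_table(model, n, as.list(res$moments_exact), as.list(res$moments), "dp")
}

#' Per-size exact moment trajectory (numeric)
#'
#' The DP moments of (A, B) at every intermediate leaf count, used to
#' monitor the O(1/n) approach of E(A_n)/n and E(B_n)/n to their limits.
#'
#' @inheritParams exact_joint_moments
#' @return a data frame with columns `n`, `E_A`, `E_B`, `V_A`, `V_B`,
#'   `Cov_AB` (numeric evaluations of the exact DP).
#' @export
exact_moment_trajectory <- function(model = c("yhk", "pda"), n,
                                    start_tree = NULL, guard = NULL) {
  model <- match.arg(model)
  start_state <- start_state_for(model, start_tree)
  rooted <- if (is.null(start_tree)) TRUE else start_tree$rooted
  if (is.null(guard)) guard <- dp_guard_default[[model]]
  if (n > guard) stop("n exceeds the state-space guard; pass `guard =` to override")
  n0 <- state_leaf_count(model, start_state, rooted)
  R <- if (model == "yhk") yhk_replacement_matrix() else pda_replacement_matrix()
  res <- dp_evolve_cpp(as.integer(start_state), R, as.integer(n - n0),
                       FALSE, TRUE)
  traj <- res$trajectory
  data.frame(n = seq(n0, n), traj)
}

# Closed forms -------------------------------------------------------------

q_fmt <- function(q) {
  if (q[1] == 0) return("0")
  num <- format(q[1], scientific = FALSE)
  if (q[2] == 1) return(num)
  paste0(num, "/", format(q[2], scientific = FALSE))
}

#' Closed-form moments of (A_n, B_n)
#'
#' Closed forms valid for n >= 7.  YHK: E(A) = n/6, E(B) = n/3,
#' V(A) = 23n/420, V(B) = 2n/45, Cov = -n/45.  PDA:
#' E(A) = n(n-1)(n-2) / (2(2n-3)(2n-5)), E(B) = n(n-1) / (2(2n-3)),
#' V(B) = n(n-1)(n-2)(n-3) / (2(2n-3)^2(2n-5)),
#' V(A) = 3(4n^3 - 40n^2 + 123n - 110) / (2(2n-5)(2n-7)(2n-9)) * V(B),
#' Cov = -V(B) / (2n-7).  Evaluated in exact rational arithmetic.  The
#' denominator shifts in E(B) and V(B) differ from some published
#' transcriptions; the forms used here are the ones confirmed by
#' exhaustive path enumeration at small n and by the exact DP for all
#' n up to 20 (see the methods vignette).
#'
#' @param model `"yhk"` or `"pda"`.
#' @param n leaf count, n >= 7 (the formulas' stated range).
#' @return a `moment_table` with source `"closed_form"`.
#' @export
closed_form_moments <- function(model = c("yhk", "pda"), n) {
  model <- match.arg(model)
  if (n < 7) stop("the closed forms hold for n >= 7")
  if (model == "yhk") {
    ex <- list(E_A = qn(n, 6), E_B = qn(n, 3), V_A = qn(23 * n, 420),
               V_B = qn(2 * n, 45), Cov_AB = qn(-n, 45))
  } else {
    E_A <- q_mul(qn(n * (n - 1), 2 * (2 * n - 3)), qn(n - 2, 2 * n - 5))
    E_B <- qn(n * (n - 1), 2 * (2 * n - 3))
    V_B <- q_mul(qn(n * (n - 1), 2 * (2 * n - 3)),
                 qn((n - 2) * (n - 3), (2 * n - 3) * (2 * n - 5)))
    fac <- qn(3 * (4 * n^3 - 40 * n^2 + 123 * n - 110),
              2 * (2 * n - 5) * (2 * n - 7) * (2 * n - 9))
    V_A <- q_mul(fac, V_B)
    Cov <- q_mul(V_B, qn(-1, 2 * n - 7))
    ex <- list(E_A = E_A, E_B = E_B, V_A = V_A, V_B = V_B, Cov_AB = Cov)
  }
  numeric <- lapply(ex, function(q) q[1] / q[2])
  moment_table(model, n, lapply(ex, q_fmt), numeric, "closed_form")
}

# Unrooted small-n enumeration ---------------------------------------------

#' Exact unrooted shape distribution by path enumeration
#'
#' Enumerates every growth path of the unrooted process from the two-leaf
#' tree.  All paths at a given size are equally likely (the number of
#' candidate edges depends only on the size, not the shape), so each
#' terminal alpha census gets probability (#paths) / (total paths) exactly.
#' Only n in 6..8 is supported: below 6 the unrooted typing is undefined,
#' above 8 the path count explodes.
#'
#' @param model `"yhk"` or `"pda"`.
#' @param n target leaf count, 6 <= n <= 8.
#' @return a data frame with one row per distinct alpha census: columns
#'   `E1`..`E4`, `paths`, `total`, `prob` (= paths/total, exact in
#'   doubles) and `prob_exact` ("p/q" reduced).
#' @export
exact_unrooted_shape_dist <- function(model = c("yhk", "pda"), n) {
  model <- match.arg(model)
  if (n < 6 || n > 8) stop("exhaustive enumeration supports 6 <= n <= 8")
  counts <- new.env(parent = emptyenv())
  recurse <- function(tree) {
    if (tree$nleaf == n) {
      key <- paste(alpha_vector(tree), collapse = ",")
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
      return(invisible())
    }
    ed <- enumerate_edges(tree)
    cand <- if (model == "yhk") ed$edge[ed$pendant] else ed$edge
    for (e in cand) recurse(attach_leaf(tree, e))
    invisible()
  }
  recurse(two_leaf_tree(rooted = FALSE))
  keys <- ls(counts)
  paths <- vapply(keys, function(k) counts[[k]], 0)
  total <- sum(paths)
  states <- do.call(rbind, lapply(strsplit(keys, ","), as.integer))
  colnames(states) <- paste0("E", 1:4)
  ord <- order(-paths)
  pe <- vapply(seq_along(paths), function(i) q_fmt(qn(paths[i], total)), "")
  out <- data.frame(states, paths = paths, total = total,
                    prob = paths / total, prob_exact = pe,
                    stringsAsFactors = FALSE)
  out[ord, , drop = FALSE]
}
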