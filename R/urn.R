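# Balanced urn engine.
#
# An urn is (C0, R): a non-negative initial configuration and a d x d
# integer replacement matrix with constant row sum s.  Drawing colour i
# (with probability C[i]/t) adds row i of R to the configuration, so the
# total grows deterministically, t_n = t_0 + n s.  Under the assumptions
# below (tenable, small, strictly balanced, diagonalisable over the reals)
# the configuration satisfies a strong law, C_n/(n s) -> v1, and a CLT,
# (C_n - n s v1)/sqrt(n) -> N(0, Sigma), where v1 is the stochastic
# principal left eigenvector and Sigma is assembled from the non-principal
# eigen-pairs:
#
#   Sigma = sum_{i,j >= 2} s li lj (u_i' diag(v1) u_j) / (s - li - lj) v_i' v_j.

#' Replacement matrix of the pendant edge-type urn (YHK growth)
#'
#' Rows give the change of the type-1..4 pendant edge census when a leaf is
#' attached to an edge of each type; every row sums to s = 1 (one new
#' pendant edge per step).
#'
#' @return a 4 x 4 integer matrix.
#' @export
yhk_replacement_matrix <- function() {
  matrix(c(0L, 0L, 0L, 1L,
           2L, -2L, 1L, 0L,
           -2L, 4L, -1L, 0L,
           0L, 2L, 0L, -1L), 4, 4, byrow = TRUE)
}

#' Replacement matrix of the full edge-type urn (PDA growth)
#'
#' Rows give the change of the type-1..6 edge census when a leaf is
#' attached to an edge of each type; every row sums to s = 2 (two new edges
#' per step).  The upper-left 4 x 4 block restricted to pendant columns is
#' the YHK matrix; selecting a type-5 edge acts like type 2 and type 6 like
#' type 1.
#'
#' @return a 6 x 6 integer matrix.
#' @export
pda_replacement_matrix <- function() {
  matrix(c(0L, 0L, 0L, 1L, 0L, 1L,
           2L, -2L, 1L, 0L, -1L, 2L,
           -2L, 4L, -1L, 0L, 2L, -1L,
           0L, 2L, 0L, -1L, 1L, 0L,
           2L, -2L, 1L, 0L, -1L, 2L,
           0L, 0L, 0L, 1L, 0L, 1L), 6, 6, byrow = TRUE)
}

#' Construct an urn specification
#'
#' @param C0 non-negative integer initial configuration with positive sum.
#' @param R integer replacement matrix with constant row sums.
#' @param model optional tag (`"yhk"` or `"pda"`) marking the built-in
#'   tree urns, whose tenability is certified by the tree semantics.
#' @return an object of class `urn_spec` with fields `d`, `C0`, `R`, `s`.
#' @export
urn_spec <- function(C0, R, model = NULL) {
  C0 <- as.numeric(C0)
  R <- as.matrix(R)
  d <- length(C0)
  if (!all(dim(R) == d)) stop("replacement matrix must be ", d, " x ", d)
  if (any(C0 < 0)) stop("initial configuration must be non-negative")
  if (sum(C0) <= 0) stop("initial configuration must contain at least one ball")
  if (any(R != round(R))) stop("replacement matrix must be integer")
  rs <- rowSums(R)
  if (max(rs) - min(rs) > 1e-12)
    stop("replacement matrix is not balanced (row sums differ)")
  structure(list(d = d, C0 = C0, R = R, s = rs[1], model = model),
            class = "urn_spec")
}

#' @export
print.urn_spec <- function(x, ...) {
  cat(sprintf("urn spec: %d colours, balance s = %g%s\n", x$d, x$s,
              if (!is.null(x$model)) paste0(" (", toupper(x$model), " edge-type urn)") else ""))
  cat(" C0:", paste(x$C0, collapse = " "), "\n")
  invisible(x)
}

#' Edge-type urn of a YHK process started at a given tree
#'
#' @param start_tree starting tree (default: the two-leaf rooted tree).
#' @return an `urn_spec` with `C0 = alpha_vector(start_tree)` and the
#'   4 x 4 pendant-type replacement matrix (s = 1).
#' @export
make_yhk_urn <- function(start_tree = NULL) {
  if (is.null(start_tree)) start_tree <- two_leaf_tree()
  urn_spec(alpha_vector(start_tree), yhk_replacement_matrix(), model = "yhk")
}

#' Edge-type urn of a PDA process started at a given tree
#'
#' @param start_tree starting tree (default: the two-leaf rooted tree).
#' @return an `urn_spec` with `C0 = beta_vector(start_tree)` and the
#'   6 x 6 edge-type replacement matrix (s = 2).
#' @export
make_pda_urn <- function(start_tree = NULL) {
  if (is.null(start_tree)) start_tree <- two_leaf_tree()
  urn_spec(beta_vector(start_tree), pda_replacement_matrix(), model = "pda")
}

# Spectral analysis -------------------------------------------------------

#' Spectral decomposition of a replacement matrix
#'
#' Computes eigenvalues in descending order, a right eigenvector matrix U
#' whose first column is the all-ones vector, and the matching left
#' eigenvectors V = U^-1 (rows), so that `V[i, ] %*% U[, j]` is the
#' Kronecker delta and `V[1, ]` is the stochastic principal left
#' eigenvector.  When all eigenvalues are integers (as for both built-in
#' urns) the decomposition is carried out in exact rational arithmetic;
#' otherwise double precision is used.
#'
#' @param spec an `urn_spec`.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` (default) tries exact and falls back to numeric.
#' @param tol numeric tolerance for realness/integrality checks.
#' @return an object of class `urn_spectral`: list with `values`, `U`,
#'   `V`, `v1`, `s`, `exact`, and (exact path) rational `U_rat`, `V_rat`.
#' @export
urn_spectral <- function(spec, exact = NULL, tol = 1e-9) {
  stopifnot(inherits(spec, "urn_spec"))
  R <- spec$R; d <- spec$d; s <- spec$s
  ee <- eigen(R)
  if (max(abs(Im(ee$values))) > tol)
    stop("complex eigenvalues: the limit theory implemented here requires a real spectrum")
  ev <- Re(ee$values)
  evi <- round(ev)
  can_exact <- all(abs(ev - evi) < 1e-7) && all(R == round(R))
  if (isTRUE(exact) && !can_exact)
    stop("exact spectral path requires an integer matrix with integer eigenvalues")
  use_exact <- if (is.null(exact)) can_exact else exact

  if (use_exact) {
    lam <- sort(unique(evi), decreasing = TRUE)
    if (abs(lam[1] - s) > 0) stop("principal eigenvalue does not equal the balance constant")
    Rq <- qm_new(R)
    cols_num <- NULL; cols_den <- NULL; values <- numeric(0)
    for (l in lam) {
      Ml <- qm_new(R - diag(l, d))
      if (l == s) {
        # convention: principal right eigenvector is the all-ones column
        if (any(R %*% rep(1, d) != s)) stop("all-ones vector is not a right eigenvector")
        ns <- qm_nullspace(Ml)
        if (ncol(ns$num) != 1L)
          stop("principal eigenvalue is not simple; the small-eigenvalue assumption fails")
        cols_num <- cbind(cols_num, rep(1, d)); cols_den <- cbind(cols_den, rep(1, d))
        values <- c(values, l)
      } else {
        ns <- qm_nullspace(Ml)
        k <- ncol(ns$num)
        if (k == 0L) next
        # clear denominators per column for readability (scale-invariant)
        for (c0 in seq_len(k)) {
          den_lcm <- 1
          for (i in seq_len(d)) den_lcm <- den_lcm / gcd1(den_lcm, ns$den[i, c0]) * ns$den[i, c0]
          cols_num <- cbind(cols_num, ns$num[, c0] * (den_lcm / ns$den[, c0]))
          cols_den <- cbind(cols_den, rep(1, d))
          values <- c(values, l)
        }
      }
    }
    if (length(values) != d)
      stop("matrix is not diagonalisable over the rationals (eigenvector defect of ",
           d - length(values), ")")
    U_rat <- qm_new(cols_num, cols_den)
    V_rat <- qm_inverse(U_rat)
    out <- list(values = values, U = qm_numeric(U_rat), V = qm_numeric(V_rat),
                v1 = qm_numeric(V_rat)[1, ], s = s, exact = TRUE,
                U_rat = U_rat, V_rat = V_rat)
  } else {
    ord <- order(ev, decreasing = TRUE)
    ev <- ev[ord]
    U <- Re(ee$vectors)[, ord, drop = FALSE]
    if (abs(ev[1] - s) > tol) stop("principal eigenvalue does not equal the balance constant")
    if (d > 1 && ev[2] > ev[1] - tol)
      stop("principal eigenvalue is not simple; the small-eigenvalue assumption fails")
    if (max(abs(R %*% rep(1, d) - s)) > tol)
      stop("all-ones vector is not a right eigenvector")
    U[, 1] <- 1
    V <- tryCatch(solve(U), error = function(e)
      stop("matrix is not diagonalisable: eigenvector matrix is singular"))
    out <- list(values = ev, U = U, V = V, v1 = V[1, ], s = s, exact = FALSE)
  }
  if (any(out$v1 < -tol))
    stop("principal left eigenvector is not stochastic (negative entries)")
  structure(out, class = "urn_spectral")
}

#' @export
print.urn_spectral <- function(x, ...) {
  cat("urn spectral data (", if (x$exact) "exact rational" else "numeric", " path)\n", sep = "")
  cat(" eigenvalues:", paste(signif(x$values, 6), collapse = ", "), "\n")
  cat(" v1:", paste(signif(x$v1, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Check the urn assumptions (tenable, small, strictly balanced, diagonalisable)
#'
#' Tenability is certified for the two built-in tree urns (their dynamics
#' mirror an actual tree process, which can never produce a negative type
#' census); for other urns it is probed empirically by simulation, reported
#' as "no violation observed".
#'
#' @param spec an `urn_spec`.
#' @param n_sims,n_steps simulated trajectories (count and length) for the
#'   empirical tenability probe.
#' @param seed optional seed for the probe.
#' @param tol numeric tolerance.
#' @return a list with entries `A1`..`A4`, each `list(pass =, note =)`,
#'   of class `urn_assumptions`.
#' @export
check_assumptions <- function(spec, n_sims = 100, n_steps = 200, seed = NULL,
                              tol = 1e-9) {
  stopifnot(inherits(spec, "urn_spec"))
  R <- spec$R; d <- spec$d; s <- spec$s
  ee <- eigen(R)$values
  real_ok <- max(abs(Im(ee))) < tol
  ev <- sort(Re(ee), decreasing = TRUE)
  small_ok <- real_ok && ev[1] > 0 && all(ev[1] > 2 * ev[-1] + tol)
  A2 <- list(pass = small_ok,
             note = sprintf("eigenvalues: %s%s",
                            paste(signif(ev, 6), collapse = ", "),
                            if (!real_ok) " (complex parts present)" else ""))
  rs <- rowSums(R)
  lv <- eigen(t(R))
  i1 <- which.min(abs(Re(lv$values) - s))
  v1 <- Re(lv$vectors[, i1]); v1 <- v1 / sum(v1)
  A3 <- list(pass = (max(rs) - min(rs) < tol) && all(v1 > -1e-9),
             note = sprintf("row sums constant (s = %g); v1 = (%s)", s,
                            paste(signif(v1, 6), collapse = ", ")))
  gm <- sum(vapply(unique(round(Re(ee), 7)), function(l)
    d - qr(R - diag(l, d), tol = 1e-7)$rank, 0))
  A4 <- list(pass = gm == d,
             note = sprintf("sum of geometric multiplicities: %d of %d", gm, d))
  if (!is.null(spec$model) && spec$model %in% c("yhk", "pda")) {
    A1 <- list(pass = TRUE,
               note = "certified: the urn mirrors a tree process whose type census cannot go negative")
  } else {
    if (!is.null(seed)) set.seed(seed)
    viol <- FALSE
    for (i in seq_len(n_sims)) {
      ok <- tryCatch({ simulate_urn(spec, n_steps); TRUE },
                     error = function(e) FALSE)
      if (!ok) { viol <- TRUE; break }
    }
    A1 <- list(pass = !viol,
               note = if (viol) "negative configuration reached in simulation"
               else sprintf("no violation observed in %d trajectories of %d steps",
                            n_sims, n_steps))
  }
  structure(list(A1 = A1, A2 = A2, A3 = A3, A4 = A4), class = "urn_assumptions")
}

#' @export
print.urn_assumptions <- function(x, ...) {
  nm <- c(A1 = "tenable", A2 = "small", A3 = "strictly balanced", A4 = "diagonalisable")
  for (k in names(nm))
    cat(sprintf(" %s (%s): %s — %s\n", k, nm[k],
                if (x[[k]]$pass) "pass" else "FAIL", x[[k]]$note))
  invisible(x)
}

# Limit laws ---------------------------------------------------------------

#' Almost-sure limit and CLT covariance of a balanced urn
#'
#' `limit_law()` returns both first- and second-order limits: the
#' per-step drift `s * v1` (the a.s. limit of C_n / n) and the covariance
#' `Sigma` of the centered, sqrt(n)-scaled configuration.
#'
#' @param spec an `urn_spec` satisfying the assumptions.
#' @param exact see [urn_spectral()].
#' @return an object of class `urn_limit_law`: list with `s`, `v1`,
#'   `mean` (= s v1), `Sigma`, `exact`, and exact rational components
#'   (`mean_rat`, `Sigma_rat`) on the exact path.
#' @export
limit_law <- function(spec, exact = NULL) {
  sp <- urn_spectral(spec, exact = exact)
  d <- length(sp$values); s <- sp$s
  if (sp$exact) {
    Dv <- qm_new(diag(d))
    for (i in seq_len(d)) Dv <- qm_set(Dv, i, i, qm_get(sp$V_rat, 1, i))
    Sig <- qm_new(matrix(0, d, d))
    for (i in seq_len(d)[-1]) for (j in seq_len(d)[-1]) {
      li <- sp$values[i]; lj <- sp$values[j]
      if (li == 0 || lj == 0) next
      ui <- list(num = sp$U_rat$num[, i, drop = FALSE], den = sp$U_rat$den[, i, drop = FALSE])
      uj <- list(num = sp$U_rat$num[, j, drop = FALSE], den = sp$U_rat$den[, j, drop = FALSE])
      m <- qm_matmul(qm_matmul(qm_transpose(ui), Dv), uj) # 1 x 1
      coef <- q_mul(qn(s * li * lj, s - li - lj), qm_get(m, 1, 1))
      vi <- list(num = sp$V_rat$num[i, , drop = FALSE], den = sp$V_rat$den[i, , drop = FALSE])
      vj <- list(num = sp$V_rat$num[j, , drop = FALSE], den = sp$V_rat$den[j, , drop = FALSE])
      term <- qm_scale(qm_matmul(qm_transpose(vi), vj), coef)
      Sig <- qm_add(Sig, term)
    }
    mean_rat <- qm_scale(list(num = sp$V_rat$num[1, , drop = FALSE],
                              den = sp$V_rat$den[1, , drop = FALSE]), qn(s))
    law <- list(s = s, v1 = sp$v1, mean = qm_numeric(mean_rat)[1, ],
                Sigma = qm_numeric(Sig), exact = TRUE,
                mean_rat = mean_rat, Sigma_rat = Sig, spectral = sp)
  } else {
    Dv <- diag(sp$v1, d)
    Sig <- matrix(0, d, d)
    for (i in seq_len(d)[-1]) for (j in seq_len(d)[-1]) {
      li <- sp$values[i]; lj <- sp$values[j]
      num <- s * li * lj * drop(crossprod(sp$U[, i], Dv %*% sp$U[, j]))
      Sig <- Sig + num / (s - li - lj) * tcrossprod(sp$V[i, ], sp$V[j, ])
    }
    law <- list(s = s, v1 = sp$v1, mean = s * sp$v1, Sigma = Sig,
                exact = FALSE, spectral = sp)
  }
  structure(law, class = "urn_limit_law")
}

#' @rdname limit_law
#' @return `limit_mean()`: the length-d vector s * v1, the a.s. limit of
#'   C_n / n.
#' @export
limit_mean <- function(spec, exact = NULL) limit_law(spec, exact = exact)$mean

#' @rdname limit_law
#' @return `limit_covariance()`: the d x d CLT covariance matrix; on the
#'   exact path it carries integer attributes `num` and `den` with
#'   `Sigma == num / den` exactly.
#' @export
limit_covariance <- function(spec, exact = NULL) {
  law <- limit_law(spec, exact = exact)
  Sig <- law$Sigma
  if (law$exact) {
    attr(Sig, "num") <- law$Sigma_rat$num
    attr(Sig, "den") <- law$Sigma_rat$den
  }
  Sig
}

#' Project an urn limit law through a linear map
#'
#' Applies a k x d matrix L to the limit law: mean `L m'`, covariance
#' `L Sigma L'`.  With `L = rbind(c(1/2, 0, ...), c(1/2, 1/2, 0, ...))`
#' this turns the edge-type law into the joint (pitchfork, cherry) law,
#' since A = alpha1 / 2 and B = (alpha1 + alpha2) / 2.
#'
#' @param law an `urn_limit_law` from [limit_law()].
#' @param L a k x d numeric matrix with small-rational entries.
#' @return an `urn_limit_law` with `mean` of length k and k x k `Sigma`.
#' @export
project_law <- function(law, L) {
  stopifnot(inherits(law, "urn_limit_law"))
  L <- as.matrix(L)
  if (ncol(L) != length(law$mean))
    stop("projection matrix has ", ncol(L), " columns; law has dimension ",
         length(law$mean))
  if (isTRUE(law$exact)) {
    Lr <- qm_new(matrix(0, nrow(L), ncol(L)))
    for (i in seq_len(nrow(L))) for (j in seq_len(ncol(L)))
      Lr <- qm_set(Lr, i, j, as_rational(L[i, j]))
    mean_rat <- qm_matmul(Lr, qm_transpose(law$mean_rat))
    Sig_rat <- qm_matmul(qm_matmul(Lr, law$Sigma_rat), qm_transpose(Lr))
    out <- list(s = law$s, v1 = law$v1, mean = drop(qm_numeric(mean_rat)),
                Sigma = qm_numeric(Sig_rat), exact = TRUE,
                mean_rat = qm_transpose(mean_rat), Sigma_rat = Sig_rat)
  } else {
    out <- list(s = law$s, v1 = law$v1, mean = drop(L %*% law$mean),
                Sigma = L %*% law$Sigma %*% t(L), exact = FALSE)
  }
  structure(out, class = "urn_limit_law")
}

#' @export
print.urn_limit_law <- function(x, ...) {
  cat("urn limit law (", if (isTRUE(x$exact)) "exact" else "numeric", ")\n", sep = "")
  cat(" mean direction:", paste(signif(x$mean, 6), collapse = ", "), "\n")
  cat(" CLT covariance:\n")
  print(signif(x$Sigma, 6))
  invisible(x)
}

# Simulation ---------------------------------------------------------------

#' Simulate an urn trajectory
#'
#' Draws colour i with probability C[i]/t and adds row i of the
#' replacement matrix.  A forced draw sequence can be supplied to replay a
#' specific path (each forced colour must be present in the urn at its
#' step).
#'
#' @param spec an `urn_spec`.
#' @param steps number of draws.
#' @param seed optional RNG seed.
#' @param draws optional integer vector of forced colours (length `steps`).
#' @return a (steps + 1) x d integer matrix of configurations, with the
#'   drawn colours in attribute `"draws"`.
#' @export
simulate_urn <- function(spec, steps, seed = NULL, draws = NULL) {
  stopifnot(inherits(spec, "urn_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(draws) && length(draws) != steps)
    stop("forced draw sequence must have length `steps`")
  d <- spec$d
  out <- matrix(0L, steps + 1L, d)
  C <- spec$C0
  out[1L, ] <- as.integer(C)
  chosen <- integer(steps)
  for (k in seq_len(steps)) {
    t <- sum(C)
    if (t <= 0) stop("urn exhausted at step ", k)
    i <- if (is.null(draws)) sample.int(d, 1L, prob = C / t) else as.integer(draws[k])
    if (C[i] <= 0) stop("forced draw of empty colour ", i, " at step ", k)
    C <- C + spec$R[i, ]
    if (any(C < 0)) stop("tenability violation at step ", k,
                         ": colour count went negative")
    out[k + 1L, ] <- as.integer(C)
    chosen[k] <- i
  }
  attr(out, "draws") <- chosen
  out
}
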