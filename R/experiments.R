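# Convergence experiments.
#
# Each experiment compares seeded Monte-Carlo estimates against analytic
# targets that are always recomputed from the urn engine (never
# hard-coded), so a regression in the spectral pipeline shows up here.
# The default tolerance is 3 standard errors.

ab_projection <- function(d) {
  # (A, B) = L %*% census with A = c1/2, B = (c1 + c2)/2
  L <- matrix(0, 2, d)
  L[1, 1] <- 0.5
  L[2, 1:2] <- 0.5
  L
}

#' Analytic (A, B) limit law for a model
#'
#' The projected urn limit law: per-leaf means of (pitchforks, cherries)
#' and the 2 x 2 CLT covariance of the centered, sqrt(n)-scaled counts.
#'
#' @param model `"yhk"` or `"pda"`.
#' @param exact see [urn_spectral()].
#' @return an `urn_limit_law` with 2-dimensional `mean` and `Sigma`.
#' @export
ab_limit_law <- function(model = c("yhk", "pda"), exact = NULL) {
  model <- match.arg(model)
  spec <- if (model == "yhk") make_yhk_urn() else make_pda_urn()
  project_law(limit_law(spec, exact = exact), ab_projection(spec$d))
}

# Mardia's multivariate skewness and kurtosis with asymptotic p-values
mardia_stats <- function(X) {
  X <- as.matrix(X)
  m <- nrow(X); p <- ncol(X)
  ctr <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(ctr) / m
  Sinv <- solve(S)
  W <- ctr %*% Sinv
  # skewness: mean over pairs of (x_i' Sinv x_j)^3, computed in row blocks
  b1 <- 0
  block <- 1024L
  for (lo in seq(1L, m, by = block)) {
    hi <- min(lo + block - 1L, m)
    G <- W[lo:hi, , drop = FALSE] %*% t(ctr)
    b1 <- b1 + sum(G^3)
  }
  b1 <- b1 / m^2
  d2 <- rowSums(W * ctr)
  b2 <- mean(d2^2)
  skew_stat <- m * b1 / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  kurt_z <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / m)
  list(skewness = b1, skewness_stat = skew_stat,
       skewness_p = stats::pchisq(skew_stat, df = skew_df, lower.tail = FALSE),
       kurtosis = b2, kurtosis_z = kurt_z,
       kurtosis_p = 2 * stats::pnorm(abs(kurt_z), lower.tail = FALSE))
}

new_report <- function(kind, config, body) {
  structure(c(list(kind = kind, config = config), body),
            class = "urn_experiment_report")
}

#' @export
print.urn_experiment_report <- function(x, ...) {
  cat("urn experiment report:", x$kind, "\n")
  cfg <- x$config
  cat(" config:", paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = "/"), ""), sep = "=", collapse = ", "), "\n")
  if (!is.null(x$table)) { cat(" summary:\n"); print(x$table, digits = 5) }
  if (!is.null(x$pass)) cat(" pass:", all(unlist(x$pass)), "\n")
  invisible(x)
}

#' Strong-law convergence experiment
#'
#' Estimates E(A_n/n, B_n/n) on a grid of sizes and compares with the
#' analytic almost-sure limit (1/6, 1/3 for YHK; 1/8, 1/4 for PDA).
#'
#' @param model `"yhk"` or `"pda"`.
#' @param rooted grow rooted (default) or unrooted trees.
#' @param n_grid ascending vector of leaf counts.
#' @param reps replicates per grid point.
#' @param seed RNG seed.
#' @param start_tree optional starting tree.
#' @param z_tol tolerance in standard errors (default 3).
#' @return an `urn_experiment_report` with a per-n summary table,
#'   z-scores, and pass flags.
#' @export
run_slln_experiment <- function(model = c("yhk", "pda"), rooted = TRUE,
                                n_grid, reps, seed = NULL, start_tree = NULL,
                                z_tol = 3) {
  model <- match.arg(model)
  stopifnot(!is.unsorted(n_grid))
  if (!is.null(seed)) set.seed(seed)
  target <- ab_limit_law(model)$mean
  rows <- lapply(n_grid, function(n) {
    ab <- sample_joint(model, n, reps, start_tree = start_tree, rooted = rooted)
    mA <- mean(ab$A / n); mB <- mean(ab$B / n)
    seA <- if (reps > 1) stats::sd(ab$A / n) / sqrt(reps) else 0
    seB <- if (reps > 1) stats::sd(ab$B / n) / sqrt(reps) else 0
    data.frame(n = n, mean_A = mA, mean_B = mB, se_A = seA, se_B = seB,
               target_A = target[1], target_B = target[2],
               z_A = if (seA > 0) (mA - target[1]) / seA else 0,
               z_B = if (seB > 0) (mB - target[2]) / seB else 0)
  })
  tab <- do.call(rbind, rows)
  new_report("slln",
             list(model = model, rooted = rooted, n_grid = n_grid,
                  reps = reps, seed = seed, z_tol = z_tol),
             list(table = tab, target = target,
                  pass = abs(c(tab$z_A, tab$z_B)) <= z_tol))
}

#' Central-limit experiment
#'
#' Compares the sample covariance of the centered, sqrt(n)-scaled
#' (A_n, B_n) with the analytic CLT covariance, and reports Mardia
#' normality diagnostics of the standardized replicates.
#'
#' @inheritParams run_slln_experiment
#' @param n leaf count.
#' @param reps number of replicates (>= 500 recommended).
#' @return an `urn_experiment_report` with the sample and target
#'   covariances, entrywise z-scores, and Mardia statistics.
#' @export
run_clt_experiment <- function(model = c("yhk", "pda"), rooted = TRUE, n, reps,
                               seed = NULL, start_tree = NULL, z_tol = 3) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  law <- ab_limit_law(model)
  mu <- law$mean; Sig <- law$Sigma
  ab <- sample_joint(model, n, reps, start_tree = start_tree, rooted = rooted)
  X <- cbind((ab$A - n * mu[1]) / sqrt(n), (ab$B - n * mu[2]) / sqrt(n))
  Shat <- stats::cov(X)
  # SE of a sample covariance entry under normality:
  # var(s_jk) = (sigma_jj sigma_kk + sigma_jk^2) / m
  se <- sqrt((outer(diag(Sig), diag(Sig)) + Sig^2) / reps)
  z <- (Shat - Sig) / se
  tab <- data.frame(entry = c("var_A", "cov_AB", "var_B"),
                    sample = c(Shat[1, 1], Shat[1, 2], Shat[2, 2]),
                    target = c(Sig[1, 1], Sig[1, 2], Sig[2, 2]),
                    se = c(se[1, 1], se[1, 2], se[2, 2]),
                    z = c(z[1, 1], z[1, 2], z[2, 2]))
  new_report("clt",
             list(model = model, rooted = rooted, n = n, reps = reps,
                  seed = seed, z_tol = z_tol),
             list(table = tab, sample_cov = Shat, target_cov = Sig,
                  mean_z = c(A = mean(X[, 1]) / (stats::sd(X[, 1]) / sqrt(reps)),
                             B = mean(X[, 2]) / (stats::sd(X[, 2]) / sqrt(reps))),
                  mardia = mardia_stats(X),
                  pass = abs(tab$z) <= z_tol))
}

#' Start-tree independence experiment
#'
#' The limiting scaled counts do not depend on the starting tree; this
#' experiment grows from several starts and z-tests all pairwise
#' differences of the mean per-leaf counts.
#'
#' @inheritParams run_clt_experiment
#' @param starts list of at least two starting `urn_tree`s.
#' @return an `urn_experiment_report` with per-start means and pairwise
#'   z-scores.
#' @export
run_start_independence_experiment <- function(model = c("yhk", "pda"), starts,
                                              n, reps, seed = NULL, z_tol = 3) {
  model <- match.arg(model)
  if (length(starts) < 2L) stop("need at least two starting trees")
  if (!is.null(seed)) set.seed(seed)
  per <- lapply(seq_along(starts), function(i) {
    ab <- sample_joint(model, n, reps, start_tree = starts[[i]])
    data.frame(start = i, n_start = starts[[i]]$nleaf,
               mean_A = mean(ab$A / n), mean_B = mean(ab$B / n),
               se_A = stats::sd(ab$A / n) / sqrt(reps),
               se_B = stats::sd(ab$B / n) / sqrt(reps))
  })
  tab <- do.call(rbind, per)
  pairs <- utils::combn(length(starts), 2)
  zt <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    zA <- (tab$mean_A[i] - tab$mean_A[j]) / sqrt(tab$se_A[i]^2 + tab$se_A[j]^2)
    zB <- (tab$mean_B[i] - tab$mean_B[j]) / sqrt(tab$se_B[i]^2 + tab$se_B[j]^2)
    c(zA, zB)
  })
  pw <- data.frame(start_i = pairs[1, ], start_j = pairs[2, ],
                   z_A = zt[1, ], z_B = zt[2, ])
  new_report("start-independence",
             list(model = model, n = n, reps = reps, seed = seed, z_tol = z_tol),
             list(table = tab, pairwise = pw,
                  pass = abs(c(pw$z_A, pw$z_B)) <= z_tol))
}
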