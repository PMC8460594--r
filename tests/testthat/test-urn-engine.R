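# Printed reference matrices used as independent fixtures for the spectral
# pipeline (right-eigenvector basis and limit covariances).

eq10_x1260 <- matrix(c(276, -388, 138, -26,
                       -388, 724, -194, -142,
                       138, -194, 69, -13,
                       -26, -142, -13, 181), 4, 4, byrow = TRUE)

eq18_x64 <- matrix(c(12, -12, 6, -6, -6, 6,
                     -12, 28, -6, -10, 14, -14,
                     6, -6, 3, -3, -3, 3,
                     -6, -10, -3, 19, -5, 5,
                     -6, 14, -3, -5, 7, -7,
                     6, -14, 3, 5, -7, 7), 6, 6, byrow = TRUE)

eq11_U <- matrix(c(1, 1, -1, -1,
                   1, 0, -1, -3,
                   1, -2, 2, 5,
                   1, 0, 2, 3), 4, 4, byrow = TRUE)

eq19_U <- matrix(c(1, 2.5, 2, 1, 1, 1,
                   1, -2, 1, 0, 1, 5,
                   1, -8, -1, 1, -3, -9,
                   1, -1, 1, 1, -3, -5,
                   1, 3, -1, 1, 1, 5,
                   1, 1, -1, -1, 1, 1), 6, 6, byrow = TRUE)

test_that("urn constructors read the censuses off the starting tree", {
  uy <- make_yhk_urn()
  expect_equal(uy$C0, c(0, 2, 0, 0))
  expect_equal(uy$s, 1)
  up <- make_pda_urn()
  expect_equal(up$C0, c(0, 2, 0, 0, 1, 0))
  expect_equal(up$s, 2)
  expect_equal(unname(rowSums(yhk_replacement_matrix())), rep(1, 4))
  expect_equal(unname(rowSums(pda_replacement_matrix())), rep(2, 6))
  u5 <- make_pda_urn(tree_t5())
  expect_equal(u5$C0, c(2, 2, 1, 0, 1, 3))
  expect_error(urn_spec(c(1, 1), matrix(c(1, 0, 1, 1), 2, 2)), "not balanced")
})

test_that("assumption checks pass for the tree urns and flag a classical Polya urn", {
  ay <- check_assumptions(make_yhk_urn())
  expect_true(all(vapply(ay, `[[`, TRUE, "pass")))
  ap <- check_assumptions(make_pda_urn())
  expect_true(all(vapply(ap, `[[`, TRUE, "pass")))
  # d = 2 identity replacement (original Polya urn): lambda2 = lambda1,
  # so the small-eigenvalue condition fails
  pol <- check_assumptions(urn_spec(c(1, 1), diag(2)), seed = 1)
  expect_false(pol$A2$pass)
})

test_that("spectral decomposition matches the known eigensystems", {
  sy <- urn_spectral(make_yhk_urn())
  expect_true(sy$exact)
  expect_equal(sy$values, c(1, 0, -2, -3))
  expect_equal(sy$v1, c(1, 1, 1 / 2, 1 / 2) / 3)
  # biorthogonality V U = I
  expect_equal(sy$V %*% sy$U, diag(4), tolerance = 1e-9)
  # recovered eigenvectors match the printed basis up to per-column scale
  for (j in 1:4) {
    cols <- cbind(sy$U[, j], eq11_U[, j])
    expect_equal(qr(cols, tol = 1e-9)$rank, 1)
  }

  sp <- urn_spectral(make_pda_urn())
  expect_equal(sp$values, c(2, 0, 0, 0, -2, -4))
  expect_equal(sp$v1, c(2, 2, 1, 3, 1, 7) / 16)
  expect_equal(sp$V %*% sp$U, diag(6), tolerance = 1e-9)

  # complex spectra are rejected (rotation-like replacement)
  rot <- urn_spec(c(1, 1, 1), matrix(c(1, 1, 0, 0, 1, 1, 1, 0, 1), 3, 3, byrow = TRUE))
  expect_error(urn_spectral(rot), "complex")
})

test_that("limit mean and covariance reproduce the printed limit laws exactly", {
  my <- limit_mean(make_yhk_urn())
  expect_equal(my, c(1 / 3, 1 / 3, 1 / 6, 1 / 6))
  expect_equal(sum(my), 1) # = s, since v1 is stochastic

  Sy <- limit_covariance(make_yhk_urn())
  expect_true(all(1260 %% attr(Sy, "den") == 0))
  expect_identical(attr(Sy, "num") * (1260 / attr(Sy, "den")), eq10_x1260)
  expect_equal(unname(rowSums(Sy)), rep(0, 4), tolerance = 1e-12) # Sigma e' = 0
  expect_true(min(eigen(Sy, symmetric = TRUE)$values) > -1e-12)   # PSD

  mp <- limit_mean(make_pda_urn())
  expect_equal(mp, c(2, 2, 1, 3, 1, 7) / 8)
  expect_equal(sum(mp), 2)

  Sp <- limit_covariance(make_pda_urn())
  expect_true(all(64 %% attr(Sp, "den") == 0))
  expect_identical(attr(Sp, "num") * (64 / attr(Sp, "den")), eq18_x64)
  expect_equal(unname(rowSums(Sp)), rep(0, 6), tolerance = 1e-12)
  expect_true(min(eigen(Sp, symmetric = TRUE)$values) > -1e-12)
})

test_that("the covariance is basis-invariant within the repeated eigenspace", {
  spec <- make_pda_urn()
  S_exact <- limit_covariance(spec, exact = TRUE)
  S_num <- limit_covariance(spec, exact = FALSE)
  expect_equal(unclass(S_num), matrix(S_exact, 6, 6), tolerance = 1e-8,
               ignore_attr = TRUE)
  # third basis: the printed eigenvector matrix, fed through the formula
  # independently of the package's eigen-decomposition
  s <- 2; lam <- c(2, 0, 0, 0, -2, -4)
  V <- solve(eq19_U)
  v1 <- V[1, ]
  S3 <- matrix(0, 6, 6)
  for (i in 2:6) for (j in 2:6) {
    S3 <- S3 + s * lam[i] * lam[j] *
      drop(t(eq19_U[, i]) %*% diag(v1) %*% eq19_U[, j]) / (s - lam[i] - lam[j]) *
      tcrossprod(V[i, ], V[j, ])
  }
  expect_equal(S3, matrix(S_exact, 6, 6), tolerance = 1e-8)
})

test_that("projection to (A, B) gives the printed joint limit laws", {
  Ly <- rbind(c(1 / 2, 0, 0, 0), c(1 / 2, 1 / 2, 0, 0))
  py <- project_law(limit_law(make_yhk_urn()), Ly)
  expect_equal(py$mean, c(1 / 6, 1 / 3))
  expect_equal(1260 * py$Sigma, matrix(c(69, -28, -28, 56), 2, 2))

  Lp <- cbind(rbind(c(1 / 2, 0), c(1 / 2, 1 / 2)), matrix(0, 2, 4))
  pp <- project_law(limit_law(make_pda_urn()), Lp)
  expect_equal(pp$mean, c(1 / 8, 1 / 4))
  expect_equal(64 * pp$Sigma, matrix(c(3, 0, 0, 4), 2, 2))

  # identity projection leaves the law unchanged
  id <- project_law(limit_law(make_yhk_urn()), diag(4))
  expect_equal(id$mean, limit_mean(make_yhk_urn()))
  expect_equal(id$Sigma, limit_covariance(make_yhk_urn()), ignore_attr = TRUE)
})

test_that("urn simulation follows the replacement dynamics", {
  u <- make_yhk_urn()
  # forced path through the worked four-step example
  path <- simulate_urn(u, 4, draws = c(2, 1, 4, 3))
  expect_identical(path[, 1:4],
                   matrix(as.integer(c(0, 2, 0, 0,
                                       2, 0, 1, 0,
                                       2, 0, 1, 1,
                                       2, 2, 1, 0,
                                       0, 6, 0, 0)), 5, 4, byrow = TRUE))
  expect_error(simulate_urn(u, 1, draws = 1L), "empty colour")

  traj <- simulate_urn(make_pda_urn(), 50, seed = 3)
  expect_equal(unname(rowSums(traj)), 3 + 2 * (0:50)) # t_n = t_0 + n s
})
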