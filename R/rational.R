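# Exact rational arithmetic on doubles used as exact integers.
#
# The spectral pipeline only ever manipulates tiny integers (replacement
# matrices are 4x4 or 6x6 with entries in -2..4, eigenvalues in -4..2), so
# numerators and denominators stay far below 2^53; every operation checks
# that bound and reduces by gcd.  A scalar rational is a length-2 double
# c(num, den) with den > 0; rational matrices are list(num =, den =).

.Q_MAX <- 2^53

q_chk <- function(x) {
  if (any(abs(x) > .Q_MAX)) stop("exact rational overflow; use the numeric path")
  x
}

gcd1 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

qn <- function(num, den = 1) {
  if (den == 0) stop("zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  if (num == 0) return(c(0, 1))
  g <- gcd1(num, den)
  q_chk(c(num / g, den / g))
}

q_add <- function(x, y) {
  g <- gcd1(x[2], y[2])
  if (g == 0) g <- 1
  qn(q_chk(x[1] * (y[2] / g) + y[1] * (x[2] / g)), q_chk(x[2] * (y[2] / g)))
}

q_sub <- function(x, y) q_add(x, c(-y[1], y[2]))

q_mul <- function(x, y) {
  if (x[1] == 0 || y[1] == 0) return(c(0, 1))
  g1 <- gcd1(x[1], y[2]); g2 <- gcd1(y[1], x[2])
  qn(q_chk((x[1] / g1) * (y[1] / g2)), q_chk((x[2] / g2) * (y[2] / g1)))
}

q_div <- function(x, y) {
  if (y[1] == 0) stop("rational division by zero")
  q_mul(x, c(y[2], y[1]))
}

# Rational matrices -------------------------------------------------------

qm_new <- function(num, den = NULL) {
  num <- as.matrix(num)
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  den <- as.matrix(den)
  stopifnot(all(dim(num) == dim(den)))
  for (i in seq_len(nrow(num))) for (j in seq_len(ncol(num))) {
    q <- qn(num[i, j], den[i, j])
    num[i, j] <- q[1]; den[i, j] <- q[2]
  }
  list(num = num, den = den)
}

qm_get <- function(M, i, j) c(M$num[i, j], M$den[i, j])

qm_set <- function(M, i, j, q) {
  M$num[i, j] <- q[1]; M$den[i, j] <- q[2]
  M
}

qm_dim <- function(M) dim(M$num)

qm_add <- function(A, B) {
  for (i in seq_len(nrow(A$num))) for (j in seq_len(ncol(A$num)))
    A <- qm_set(A, i, j, q_add(qm_get(A, i, j), qm_get(B, i, j)))
  A
}

qm_scale <- function(M, q) {
  for (i in seq_len(nrow(M$num))) for (j in seq_len(ncol(M$num)))
    M <- qm_set(M, i, j, q_mul(qm_get(M, i, j), q))
  M
}

qm_matmul <- function(A, B) {
  da <- qm_dim(A); db <- qm_dim(B)
  stopifnot(da[2] == db[1])
  out <- qm_new(matrix(0, da[1], db[2]))
  for (i in seq_len(da[1])) for (j in seq_len(db[2])) {
    acc <- c(0, 1)
    for (k in seq_len(da[2]))
      acc <- q_add(acc, q_mul(qm_get(A, i, k), qm_get(B, k, j)))
    out <- qm_set(out, i, j, acc)
  }
  out
}

qm_transpose <- function(M) list(num = t(M$num), den = t(M$den))

qm_numeric <- function(M) M$num / M$den

# Gauss-Jordan inverse; stops when singular
qm_inverse <- function(A) {
  d <- nrow(A$num)
  stopifnot(ncol(A$num) == d)
  W <- qm_new(cbind(A$num, diag(d)), cbind(A$den, matrix(1, d, d)))
  for (col in seq_len(d)) {
    piv <- which(W$num[col:d, col] != 0)[1]
    if (is.na(piv)) stop("rational matrix is singular")
    piv <- piv + col - 1L
    if (piv != col) {
      W$num[c(col, piv), ] <- W$num[c(piv, col), ]
      W$den[c(col, piv), ] <- W$den[c(piv, col), ]
    }
    pq <- qm_get(W, col, col)
    for (j in seq_len(2 * d)) W <- qm_set(W, col, j, q_div(qm_get(W, col, j), pq))
    for (i in seq_len(d)) {
      if (i == col || W$num[i, col] == 0) next
      f <- qm_get(W, i, col)
      for (j in seq_len(2 * d))
        W <- qm_set(W, i, j, q_sub(qm_get(W, i, j), q_mul(f, qm_get(W, col, j))))
    }
  }
  list(num = W$num[, d + seq_len(d), drop = FALSE],
       den = W$den[, d + seq_len(d), drop = FALSE])
}

# Null space of a rational matrix via reduced row echelon form.
# Returns a d x k rational matrix whose columns form a canonical basis.
qm_nullspace <- function(A) {
  W <- qm_new(A$num, A$den)
  nr <- nrow(W$num); nc <- ncol(W$num)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    piv <- which(W$num[row:nr, col] != 0)[1]
    if (is.na(piv)) next
    piv <- piv + row - 1L
    if (piv != row) {
      W$num[c(row, piv), ] <- W$num[c(piv, row), ]
      W$den[c(row, piv), ] <- W$den[c(piv, row), ]
    }
    pq <- qm_get(W, row, col)
    for (j in seq_len(nc)) W <- qm_set(W, row, j, q_div(qm_get(W, row, j), pq))
    for (i in seq_len(nr)) {
      if (i == row || W$num[i, col] == 0) next
      f <- qm_get(W, i, col)
      for (j in seq_len(nc))
        W <- qm_set(W, i, j, q_sub(qm_get(W, i, j), q_mul(f, qm_get(W, row, j))))
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  free <- setdiff(seq_len(nc), pivots)
  if (!length(free)) return(qm_new(matrix(0, nc, 0)))
  basis <- qm_new(matrix(0, nc, length(free)))
  for (k in seq_along(free)) {
    fc <- free[k]
    basis <- qm_set(basis, fc, k, c(1, 1))
    for (r in seq_along(pivots)) {
      q <- qm_get(W, r, fc)
      basis <- qm_set(basis, pivots[r], k, c(-q[1], q[2]))
    }
  }
  basis
}

# Continued-fraction rationalization of a numeric value (small denominators)
as_rational <- function(x, max_den = 1e6, tol = 1e-9) {
  if (abs(x - round(x)) < tol) return(c(round(x), 1))
  # Stern-Brocot style convergents
  a0 <- floor(x); frac <- x - a0
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  a <- a0
  repeat {
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) stop("value is not a small rational: ", x)
    if (abs(x - h / k) < tol) return(qn(h, k))
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    frac <- 1 / frac
    a <- floor(frac)
    frac <- frac - a
  }
}
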