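#' Proximal operator of the l2,1 norm (row-wise shrinkage)
#'
#' Minimises `0.5 * ||E - A||_F^2 + t * ||E||_{2,1}` where the l2,1 norm is the
#' sum of row l2 norms: each row is scaled by `max(0, 1 - t / ||row||)`, so
#' whole rows are shrunk toward zero (row-sparse noise).
#'
#' @param A numeric matrix.
#' @param t nonnegative threshold.
#' @return matrix of the same shape.
#' @export
l21_prox <- function(A, t) {
  if (t < 0) stop("t must be nonnegative")
  if (t == 0) return(A)
  norms <- sqrt(rowSums(A^2))
  scale <- pmax(0, 1 - t / pmax(norms, .Machine$double.xmin))
  A * scale
}

#' Singular value thresholding (proximal operator of the nuclear norm)
#'
#' Minimises `0.5 * ||B - A||_F^2 + t * ||B||_*` by soft-thresholding the
#' singular values of `A`.
#'
#' @param A numeric matrix.
#' @param t nonnegative threshold.
#' @return list with `B` (the thresholded matrix) and `d` (its singular
#'   values after shrinkage; `sum(d)` is the nuclear norm of `B`).
#' @export
svt <- function(A, t) {
  if (t < 0) stop("t must be nonnegative")
  s <- svd(A)
  d <- pmax(s$d - t, 0)
  keep <- d > 0
  B <- if (any(keep))
    s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
  else matrix(0, nrow(A), ncol(A))
  list(B = B, d = d)
}

# Euclidean projection of a vector onto the probability simplex
# (sum = 1, nonnegative); standard sort-based algorithm.
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Project each row onto the probability simplex with a zero diagonal
#'
#' Row i's off-diagonal entries are replaced by their Euclidean projection
#' onto the simplex (nonnegative, summing to one); the diagonal is forced to
#' zero. This enforces the representation constraints
#' `diag(Z) = 0, z_ij >= 0, sum_j z_ij = 1` exactly.
#'
#' @param Z square numeric matrix, `n >= 2`.
#' @return projected matrix.
#' @export
project_row_simplex_zero_diag <- function(Z) {
  n <- nrow(Z)
  if (n < 2L || ncol(Z) != n) stop("Z must be square with n >= 2")
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    off <- Z[i, -i]
    out[i, -i] <- project_simplex(off)
  }
  out
}
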