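#' Pairwise squared Euclidean distances between cells
#'
#' Distances are between columns of `X` (cells). Computed via the Gram-matrix
#' identity with a symmetric, zero-diagonal, nonnegative guarantee (rounding
#' can otherwise produce tiny negatives).
#'
#' @param X numeric matrix, features x cells.
#' @return n x n matrix of squared distances.
#' @export
pairwise_sqdist <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  sq <- colSums(X^2)
  D <- outer(sq, sq, "+") - 2 * crossprod(X)
  D[D < 0] <- 0
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' Build the weighted distance-penalty graph for one omics view
#'
#' For each cell j, its `knn_k` nearest neighbours (smallest squared distance,
#' ties broken by lower index, never itself) receive the Gaussian weight
#' `p_ij = exp(-d_ij / (2 sigma^2))`; every other pair keeps weight 1. Near
#' neighbours therefore pay a reduced distance penalty `Q_ij = p_ij * d_ij`,
#' which biases the representation learned by the solver toward large
#' affinities among neighbours. P is directional (column j's neighbour set
#' defines column j of P) and is not symmetrised.
#'
#' @param X numeric matrix, features x cells.
#' @param knn_k neighbourhood size, `1 <= knn_k < n`.
#' @param sigma Gaussian bandwidth, positive.
#' @return a `penalty_graph` list with `P`, `D`, `Q` (all n x n), plus
#'   `neighbors` (n x knn_k matrix of neighbour indices per cell) and the
#'   parameters used.
#' @export
build_penalty_graph <- function(X, knn_k = 10L, sigma = 1) {
  X <- as.matrix(X)
  n <- ncol(X)
  knn_k <- as.integer(knn_k)
  if (knn_k < 1L || knn_k >= n)
    stop("knn_k must satisfy 1 <= knn_k < n (n = ", n, ")")
  if (sigma <= 0) stop("sigma must be positive")
  D <- pairwise_sqdist(X)
  P <- matrix(1, n, n)
  nb <- matrix(0L, n, knn_k)
  for (j in seq_len(n)) {
    d <- D[, j]
    d[j] <- Inf                       # a cell is never its own neighbour
    idx <- order(d, seq_len(n))[seq_len(knn_k)]  # ties: lower index wins
    nb[j, ] <- idx
    P[idx, j] <- exp(-D[idx, j] / (2 * sigma^2))
  }
  structure(list(P = P, D = D, Q = P * D, neighbors = nb,
                 knn_k = knn_k, sigma = sigma),
            class = "penalty_graph")
}

#' @export
print.penalty_graph <- function(x, ...) {
  cat(sprintf("penalty_graph: n = %d, knn_k = %d, sigma = %g\n",
              nrow(x$P), x$knn_k, x$sigma))
  invisible(x)
}
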