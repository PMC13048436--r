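#' Fuse per-view representations
#'
#' The fused affinity is the plain elementwise sum `Z* = sum_v Z^v`; no
#' normalisation is applied.
#'
#' @param Zs list of n x n matrices.
#' @return n x n matrix.
#' @export
fuse_representations <- function(Zs) {
  if (!is.list(Zs) || length(Zs) < 1L) stop("need at least one matrix")
  dims <- vapply(Zs, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("all matrices must share the same shape")
  Reduce(`+`, Zs)
}

#' Information-retention ratio
#'
#' `tau = eps1 + 1 / (eps2 * n + eps3)`, in percent, clipped at 100. Larger
#' sample sizes retain a smaller fraction of the fused affinity mass, because
#' bigger matrices carry proportionally more redundant small entries.
#'
#' @param n number of cells.
#' @param eps numeric triple (eps1, eps2, eps3) with `eps2 * n + eps3 > 0`.
#' @return tau in (0, 100].
#' @export
compute_tau <- function(n, eps = c(85, 0.001, 1)) {
  stopifnot(length(eps) == 3)
  den <- eps[2] * n + eps[3]
  if (den <= 0) stop("eps2 * n + eps3 must be positive")
  tau <- eps[1] + 1 / den
  if (tau <= 0) stop("tau must be positive; got ", tau)
  min(tau, 100)
}

#' Column-wise truncation of a fused affinity matrix
#'
#' For each column, entries are ranked in descending order (ties broken by
#' lower row index) and the shortest prefix whose cumulative sum first reaches
#' `tau`% of the column total is retained; all other entries are zeroed.
#'
#' @param Zstar n x n nonnegative matrix.
#' @param tau retention percentage in (0, 100].
#' @return truncated matrix.
#' @export
simplify_affinity <- function(Zstar, tau) {
  if (any(Zstar < 0)) stop("Zstar must be nonnegative")
  if (tau <= 0 || tau > 100) stop("tau must be in (0, 100]")
  out <- matrix(0, nrow(Zstar), ncol(Zstar))
  for (j in seq_len(ncol(Zstar))) {
    col <- Zstar[, j]
    total <- sum(col)
    if (total <= 0) next
    ord <- order(col, seq_along(col), decreasing = c(TRUE, FALSE),
                 method = "radix")
    keep_n <- which(cumsum(col[ord]) >= (tau / 100) * total)[1L]
    keep <- ord[seq_len(keep_n)]
    out[keep, j] <- col[keep]
  }
  out
}

#' Angle-information similarity from a truncated affinity
#'
#' Takes the skinny SVD `Z = U L V'` (singular values above
#' `rank_tol * sigma_max` retained), forms the angle-information matrix
#' `M = U L` (one row per cell), and defines
#' `W_ij = (cos angle(m_i, m_j))^exponent`. With the default even exponent all
#' entries are nonnegative, rows of M from the same low-rank subspace give
#' large `W_ij`, and rows from orthogonal subspaces give 0. Cells with a zero
#' row of M get `W_ij = 0` everywhere (including the diagonal).
#'
#' @param Ztrunc n x n matrix (typically the output of [simplify_affinity()]).
#' @param exponent positive integer, default 2.
#' @param rank_tol relative singular-value cutoff for the skinny SVD.
#' @return list with `M` (n x r) and `W` (n x n symmetric, entries in [0, 1]).
#' @export
angle_similarity <- function(Ztrunc, exponent = 2L, rank_tol = 1e-8) {
  if (!all(is.finite(Ztrunc))) stop("Ztrunc must be finite")
  s <- svd(Ztrunc)
  if (s$d[1L] <= 0) stop("degenerate input: all singular values are zero")
  r <- sum(s$d > rank_tol * s$d[1L])
  M <- s$u[, seq_len(r), drop = FALSE] %*% diag(s$d[seq_len(r)], r)
  norms <- sqrt(rowSums(M^2))
  nz <- norms > 0
  Cmat <- tcrossprod(M) / outer(pmax(norms, .Machine$double.xmin),
                                pmax(norms, .Machine$double.xmin))
  Cmat[!nz, ] <- 0
  Cmat[, !nz] <- 0
  Cmat <- pmin(pmax(Cmat, -1), 1)
  W <- Cmat^exponent
  diag(W)[nz] <- 1
  W <- (W + t(W)) / 2
  list(M = M, W = W)
}

#' Estimate the number of clusters by the eigengap heuristic
#'
#' Computes the symmetric normalised Laplacian of `W` (isolated cells first
#' get unit self-similarity so degrees are positive), sorts its eigenvalues
#' ascending, and returns the `k` in `1..k_max` maximising
#' `lambda_{k+1} - lambda_k`.
#'
#' @param W symmetric nonnegative similarity matrix.
#' @param k_max largest cluster count considered; must be `< n`.
#' @return integer cluster count.
#' @export
eigengap_k <- function(W, k_max = 10L) {
  n <- nrow(W)
  if (k_max >= n) stop("k_max must be smaller than n")
  ev <- laplacian_spectrum(W)$values
  gaps <- diff(ev[seq_len(k_max + 1L)])
  which.max(gaps)
}

# symmetric normalised Laplacian; returns ascending eigenvalues and vectors
laplacian_spectrum <- function(W) {
  W <- (W + t(W)) / 2
  deg <- rowSums(W)
  iso <- deg <= 0
  if (any(iso)) {              # isolated cells: unit self-similarity
    diag(W)[iso] <- 1
    deg <- rowSums(W)
  }
  dinv <- 1 / sqrt(deg)
  Lsym <- diag(nrow(W)) - (dinv * W) * rep(dinv, each = nrow(W))
  e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  list(values = rev(e$values), vectors = e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE])
}

#' Normalised spectral clustering
#'
#' Embeds cells in the bottom-K eigenvectors of the symmetric normalised
#' Laplacian, normalises each row to unit length, and partitions with seeded
#' multi-restart k-means. Deterministic given `seed`.
#'
#' @param W symmetric nonnegative similarity matrix.
#' @param K number of clusters, `1 <= K <= n`.
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @return a `clustering_result` list: integer `labels`, `n_clusters`, and the
#'   ascending Laplacian `eigenvalues` used.
#' @export
spectral_cluster <- function(W, K, seed = 0L, nstart = 10L) {
  n <- nrow(W)
  if (K < 1L || K > n) stop("K must be in 1..n")
  sp <- laplacian_spectrum(W)
  if (K == 1L) {
    labels <- rep(1L, n)
  } else if (K == n) {
    labels <- seq_len(n)
  } else {
    U <- sp$vectors[, seq_len(K), drop = FALSE]
    rn <- sqrt(rowSums(U^2))
    U <- U / pmax(rn, .Machine$double.xmin)
    labels <- with_seed(seed, {
      km <- stats::kmeans(U, centers = K, nstart = nstart, iter.max = 100L)
      km$cluster
    })
  }
  structure(list(labels = as.integer(labels), n_clusters = as.integer(K),
                 eigenvalues = sp$values),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d cells in %d clusters (sizes: %s)\n",
              length(x$labels), x$n_clusters,
              paste(tabulate(x$labels), collapse = " ")))
  invisible(x)
}

# run thunk under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
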