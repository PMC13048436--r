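#' Clustering accuracy under optimal label matching
#'
#' The maximum, over one-to-one matchings between predicted clusters and true
#' classes, of the fraction of correctly assigned cells; computed by solving a
#' linear assignment problem on the contingency table (Hungarian algorithm).
#' Invariant to relabelling of either partition.
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @return accuracy in [0, 1].
#' @export
clustering_acc <- function(true_labels, pred_labels) {
  check_label_pair(true_labels, pred_labels)
  tab <- table(factorize_labels(true_labels), factorize_labels(pred_labels))
  k <- max(dim(tab))
  cont <- matrix(0, k, k)                 # pad to square with empty clusters
  cont[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  match_cols <- hungarian_min(-cont)
  sum(cont[cbind(seq_len(k), match_cols)]) / length(true_labels)
}

#' Normalised mutual information of two partitions
#'
#' Mutual information normalised by the arithmetic mean of the two partition
#' entropies (natural log). Returns 0 when exactly one partition is trivial
#' (single cluster), and 1 when both are trivial (they are then identical).
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @return NMI in [0, 1].
#' @export
clustering_nmi <- function(true_labels, pred_labels) {
  check_label_pair(true_labels, pred_labels)
  n <- length(true_labels)
  joint <- table(true_labels, pred_labels) / n
  px <- rowSums(joint); py <- colSums(joint)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  pj <- as.numeric(joint)
  pp <- as.numeric(outer(px, py))
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / pp[nz]))
  mi / ((hx + hy) / 2)
}

#' K-nearest-neighbour label agreement in an embedding
#'
#' Measures local-structure preservation: the mean, over cells, of the
#' fraction of each cell's `k` nearest neighbours in the embedding (Euclidean
#' distance, self excluded, ties broken by lower index) that share the cell's
#' true label. The angle-information matrix `M` is the natural embedding.
#'
#' @param embedding n x r matrix, one row per cell.
#' @param true_labels length-n label vector.
#' @param k neighbourhood size, `1 <= k < n`.
#' @return agreement in [0, 1].
#' @export
kna <- function(embedding, true_labels, k = 10L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (length(true_labels) != n)
    stop("labels must match the number of embedding rows")
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
  D <- pairwise_sqdist(t(embedding))
  lab <- factorize_labels(true_labels)
  hits <- vapply(seq_len(n), function(i) {
    d <- D[i, ]
    d[i] <- Inf
    idx <- order(d, seq_len(n))[seq_len(k)]
    mean(lab[idx] == lab[i])
  }, numeric(1))
  mean(hits)
}

#' Composite score balancing accuracy and agreement across datasets
#'
#' The mean, over datasets, of the harmonic mean `2*ACC*NMI / (ACC + NMI)`
#' (0 where both are 0). This combiner rewards methods that score well on both
#' global metrics simultaneously rather than trading one for the other; it is
#' this package's documented default, pluggable via `combiner`.
#'
#' @param acc_values,nmi_values equal-length nonempty numeric vectors of
#'   per-dataset scores.
#' @param combiner function of two numeric vectors returning per-dataset
#'   combined scores.
#' @return composite score.
#' @export
breakthrough_score <- function(acc_values, nmi_values,
                               combiner = harmonic_mean_pair) {
  if (length(acc_values) != length(nmi_values) || length(acc_values) == 0)
    stop("acc_values and nmi_values must be equal-length and nonempty")
  mean(combiner(acc_values, nmi_values))
}

harmonic_mean_pair <- function(a, b) {
  out <- numeric(length(a))
  nz <- (a + b) > 0
  out[nz] <- 2 * a[nz] * b[nz] / (a[nz] + b[nz])
  out
}

#' Evaluate a clustering against truth
#'
#' Convenience wrapper computing ACC, NMI and (when an embedding is supplied)
#' KNA at one or more neighbourhood sizes.
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @param embedding optional n x r embedding for KNA.
#' @param kna_k neighbourhood sizes for KNA.
#' @return named list with `acc`, `nmi`, and `kna` (named numeric vector or
#'   `NULL`).
#' @export
evaluate_clustering <- function(true_labels, pred_labels, embedding = NULL,
                                kna_k = c(10L, 20L, 30L)) {
  out <- list(acc = clustering_acc(true_labels, pred_labels),
              nmi = clustering_nmi(true_labels, pred_labels),
              kna = NULL)
  if (!is.null(embedding)) {
    kna_k <- kna_k[kna_k < nrow(as.matrix(embedding))]
    out$kna <- vapply(kna_k, function(k) kna(embedding, true_labels, k),
                      numeric(1))
    names(out$kna) <- paste0("k", kna_k)
  }
  out
}

check_label_pair <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1L)
    stop("label vectors must be nonempty and of equal length")
}

# Hungarian algorithm (shortest augmenting path with potentials) for the
# minimum-cost perfect matching of a square cost matrix. Returns, for each
# row, its assigned column. O(k^3).
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  virt <- n + 1L                       # virtual column
  u <- numeric(n)
  v <- numeric(virt)
  p <- integer(virt)                   # p[j]: row matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[virt] <- i
    j0 <- virt
    minv <- rep(Inf, n)
    used <- logical(virt)
    way <- integer(n)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(virt)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {                           # augment along the recorded path
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == virt) break
    }
  }
  assign_col <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) assign_col[p[j]] <- j
  assign_col
}
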