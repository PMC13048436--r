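# Independent numeric/enumeration oracles used across the test files.

# Euclidean projection onto the probability simplex by exhaustive active-set
# enumeration with a KKT check (exact for small dimension).
simplex_project_oracle <- function(v) {
  d <- length(v)
  best <- NULL; best_obj <- Inf
  for (mask in 0:(2^d - 2)) {            # mask bit = coordinate forced to zero
    zero <- as.logical(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1))))
    free <- !zero
    k <- sum(free)
    theta <- (sum(v[free]) - 1) / k
    x <- numeric(d)
    x[free] <- v[free] - theta
    if (any(x[free] < -1e-12)) next      # infeasible active set
    obj <- sum((x - v)^2)
    if (obj < best_obj) { best_obj <- obj; best <- x }
  }
  best
}

# smooth-objective minimiser via BFGS from several starts
optim_oracle <- function(par0, fn, reltol = 1e-14, restarts = 2) {
  best <- NULL
  for (r in seq_len(restarts)) {
    start <- if (r == 1) par0 else par0 + stats::rnorm(length(par0), sd = 0.1)
    fit <- stats::optim(start, fn, method = "BFGS",
                        control = list(maxit = 2000, reltol = reltol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$par
}

# prox of t*||.||_* via the Moreau identity: A minus the projection of A onto
# the spectral-norm ball of radius t (clip singular values at t).
svt_oracle <- function(A, t) {
  s <- svd(A)
  proj <- s$u %*% (pmin(s$d, t) * t(s$v))
  A - proj
}

# clustering accuracy by exhaustive enumeration of one-to-one matchings
acc_oracle <- function(true_labels, pred_labels) {
  tl <- as.integer(factor(true_labels)); pl <- as.integer(factor(pred_labels))
  k <- max(max(tl), max(pl))
  cont <- matrix(0, k, k)
  for (i in seq_along(tl)) cont[tl[i], pl[i]] <- cont[tl[i], pl[i]] + 1
  perms <- all_permutations(k)
  best <- 0
  for (p in perms) best <- max(best, sum(cont[cbind(seq_len(k), p)]))
  best / length(tl)
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1)) {
    for (pos in seq_len(k)) out[[length(out) + 1L]] <- append(p, k, after = pos - 1)
  }
  out
}

# tiny paired two-view dataset with clear 3-cluster structure
tiny_dataset <- function(n = 60, dims = c(40, 70), seed = 1, ...) {
  generate_multiomics(synth_spec(n_cells = n, n_clusters = 3, view_dims = dims,
                                 seed = seed, ...))
}
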