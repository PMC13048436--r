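#' Fit the multi-view low-rank representation model
#'
#' Solves, by an inexact augmented-Lagrangian scheme with alternating block
#' updates, the joint problem
#' \deqn{\min \|C^*\|_* + \sum_v \big( \lambda_1 \sum_{ij} p^v_{ij}
#'   \|x^v_i - x^v_j\|^2 z^v_{ij} + w^v \|C^v - C^*\|_F^2 +
#'   \lambda_2 \|E^v\|_{2,1} \big)}
#' subject to \eqn{X^v = X^v Z^v + E^v}, \eqn{Z^v = L^v C^v R^{vT}} with
#' orthonormal \eqn{L^v, R^v}, and \eqn{diag(Z^v) = 0}, \eqn{z^v_{ij} \ge 0},
#' \eqn{\sum_j z^v_{ij} = 1}. Each cell is represented as a convex
#' combination of the other cells in every omics layer; the Gaussian-weighted
#' distance penalty biases those affinities toward k-nearest neighbours, the
#' shared low-rank consensus core ties the layers together with adaptive
#' per-layer weights, and the l2,1 term absorbs row-structured noise.
#'
#' All equality-constraint handling (multipliers `Y1`, `Y2`, penalty parameter
#' `mu` growing geometrically to `mu_max`) is standard inexact ALM; every
#' block update is in closed form. The run is fully deterministic.
#'
#' @param dataset a `multi_omics_dataset` (see [assemble_dataset()]).
#' @param config a `run_config` (see [solver_config()]).
#' @param graphs optional list of precomputed `penalty_graph`s, one per view.
#' @return a `solver_state` list: per-view `Z`, `L`, `R`, `C`, `E`, multipliers,
#'   shared consensus `Cstar`, weights `w`, `mu`, `iterations`, `converged`,
#'   and `trace` (a data.frame with the per-iteration objective breakdown:
#'   `nuclear`, `penalty`, `consensus`, `noise`, `total`, plus the two
#'   equality residuals in max norm).
#' @export
solve_multiomics <- function(dataset, config = solver_config(), graphs = NULL) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  n <- dataset$n_cells
  V <- dataset$n_views
  if (n < 3L) stop("need at least 3 cells")
  if (config$knn_k >= n)
    stop("knn_k (", config$knn_k, ") must be smaller than the number of cells (", n, ")")
  if (is.null(graphs))
    graphs <- lapply(dataset$views, build_penalty_graph,
                     knn_k = config$knn_k, sigma = config$sigma)

  Xs <- dataset$views
  pre <- lapply(Xs, function(X) {
    XtX <- crossprod(X)
    list(X = X, XtX = XtX, chol = chol(XtX + diag(n)))
  })

  # initialisation: warm-start Z from the row-normalised KNN affinity
  Z <- lapply(seq_len(V), function(v) init_affinity(graphs[[v]], config$sigma))
  L <- replicate(V, diag(n), simplify = FALSE)
  R <- replicate(V, diag(n), simplify = FALSE)
  C <- Z
  Cstar <- Reduce(`+`, C) / V
  E  <- lapply(Xs, function(X) matrix(0, nrow(X), ncol(X)))
  Y1 <- lapply(Xs, function(X) matrix(0, nrow(X), ncol(X)))
  Y2 <- replicate(V, matrix(0, n, n), simplify = FALSE)
  w  <- rep(1 / V, V)
  mu <- config$mu0
  LCRt <- lapply(seq_len(V), function(v) L[[v]] %*% C[[v]] %*% t(R[[v]]))

  trace <- vector("list", config$max_iter)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(config$max_iter)) {
    # -- Z blocks
    for (v in seq_len(V)) {
      XtF <- crossprod(pre[[v]]$X, E[[v]] - Y1[[v]] / mu)
      Z[[v]] <- update_Z(pre[[v]], XtF, LCRt[[v]], Y2[[v]],
                         graphs[[v]]$Q, config$lambda1, mu)
      check_finite(Z[[v]], iter, "Z")
    }
    # -- orthonormal factors, view cores, consensus, weights
    for (v in seq_len(V)) {
      Zt <- Z[[v]] + Y2[[v]] / mu
      lr <- update_LR(Zt, C[[v]], L[[v]], R[[v]])
      L[[v]] <- lr$L; R[[v]] <- lr$R
      C[[v]] <- update_C_view(Zt, L[[v]], R[[v]], Cstar, w[v], mu)
      check_finite(C[[v]], iter, "C")
    }
    cons <- update_consensus(C, w)
    Cstar <- cons$Cstar
    w <- update_weights(C, Cstar)
    # -- noise blocks and multipliers
    r1 <- r2 <- 0
    noise_obj <- 0
    for (v in seq_len(V)) {
      XmXZ <- pre[[v]]$X - pre[[v]]$X %*% Z[[v]]
      E[[v]] <- l21_prox(XmXZ + Y1[[v]] / mu, config$lambda2 / mu)
      res1 <- XmXZ - E[[v]]
      Y1[[v]] <- Y1[[v]] + mu * res1
      LCRt[[v]] <- L[[v]] %*% C[[v]] %*% t(R[[v]])
      res2 <- Z[[v]] - LCRt[[v]]
      Y2[[v]] <- Y2[[v]] + mu * res2
      check_finite(E[[v]], iter, "E")
      r1 <- max(r1, max(abs(res1)))
      r2 <- max(r2, max(abs(res2)))
      noise_obj <- noise_obj + sum(sqrt(rowSums(E[[v]]^2)))
    }
    mu <- min(config$rho * mu, config$mu_max)

    penalty_obj <- config$lambda1 *
      sum(vapply(seq_len(V), function(v) sum(graphs[[v]]$Q * Z[[v]]), numeric(1)))
    consensus_obj <- sum(vapply(seq_len(V), function(v)
      w[v] * sum((C[[v]] - Cstar)^2), numeric(1)))
    total <- cons$nuclear + penalty_obj + consensus_obj + config$lambda2 * noise_obj
    z_err <- max(vapply(Z, function(Zv)
      max(max(abs(diag(Zv))), max(0, -min(Zv)), max(abs(rowSums(Zv) - 1))),
      numeric(1)))
    orth_err <- max(vapply(seq_len(V), function(v)
      max(max(abs(crossprod(L[[v]]) - diag(n))),
          max(abs(crossprod(R[[v]]) - diag(n)))), numeric(1)))
    trace[[iter]] <- c(nuclear = cons$nuclear, penalty = penalty_obj,
                       consensus = consensus_obj,
                       noise = config$lambda2 * noise_obj, total = total,
                       resid_selfrep = r1, resid_factor = r2, mu = mu,
                       z_constraint_err = z_err, lr_orth_err = orth_err,
                       w_min = min(w))
    if (config$verbose)
      message(sprintf("iter %3d  obj %.6g  r1 %.3g  r2 %.3g", iter, total, r1, r2))
    if (max(r1, r2) < config$tolerance) { converged <- TRUE; break }
  }

  structure(
    list(Z = Z, L = L, R = R, C = C, E = E, Cstar = Cstar, w = w,
         Y1 = Y1, Y2 = Y2, mu = mu, iterations = iter, converged = converged,
         trace = as.data.frame(do.call(rbind, trace[seq_len(iter)])),
         graphs = graphs, config = config),
    class = "solver_state"
  )
}

#' @export
print.solver_state <- function(x, ...) {
  cat(sprintf("solver_state: %d view(s), n = %d, %d iteration(s), %s\n",
              length(x$Z), nrow(x$Cstar), x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  final objective %.6g, view weights: %s\n",
              x$trace$total[x$iterations],
              paste(signif(x$w, 3), collapse = " ")))
  invisible(x)
}

check_finite <- function(M, iter, block) {
  if (!all(is.finite(M)))
    stop("solver diverged: non-finite values in block ", block,
         " at iteration ", iter)
}

# row-normalised Gaussian affinity restricted to each cell's KNN
init_affinity <- function(graph, sigma) {
  n <- nrow(graph$D)
  Z0 <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- graph$neighbors[i, ]
    wts <- exp(-graph$D[i, idx] / (2 * sigma^2))
    if (sum(wts) <= 0) wts <- rep(1, length(idx))
    Z0[i, idx] <- wts / sum(wts)
  }
  Z0
}

# Z block: unconstrained quadratic minimiser, then projection onto the
# zero-diagonal row simplex. (X'X + I) Z = X'(X - E + Y1/mu) + LCR' - Y2/mu
# - (lambda1/mu) Q; XtF = X'(E - Y1/mu) is precomputed by the caller.
update_Z <- function(pre, XtF, LCRt, Y2, Q, lambda1, mu, project = TRUE) {
  rhs <- pre$XtX - XtF + LCRt - Y2 / mu - (lambda1 / mu) * Q
  Zunc <- backsolve(pre$chol, backsolve(pre$chol, rhs, transpose = TRUE))
  if (project) project_row_simplex_zero_diag(Zunc) else Zunc
}

# nearest orthogonal matrix maximising trace(O'G)
procrustes <- function(G) {
  s <- svd(G)
  s$u %*% t(s$v)
}

# orthogonal-Procrustes updates for the two side factors of Z ~ L C R'
update_LR <- function(Ztilde, C, L, R) {
  L <- procrustes(Ztilde %*% R %*% t(C))
  R <- procrustes(t(Ztilde) %*% L %*% C)
  list(L = L, R = R)
}

# core matrix: exact minimiser of (mu/2)||Ztilde - L C R'||_F^2 + w||C - Cstar||_F^2
# for orthonormal L, R
update_C_view <- function(Ztilde, L, R, Cstar, w, mu) {
  stopifnot(mu + 2 * w > 0)
  (mu * crossprod(L, Ztilde) %*% R + 2 * w * Cstar) / (mu + 2 * w)
}

# consensus: exact minimiser of ||C||_* + sum_v w_v ||C_v - C||_F^2
update_consensus <- function(Cs, w) {
  S <- sum(w)
  if (S <= 0) stop("view weights must sum to a positive value")
  Cbar <- Reduce(`+`, Map(`*`, Cs, w)) / S
  res <- svt(Cbar, 1 / (2 * S))
  list(Cstar = res$B, nuclear = sum(res$d))
}

# adaptive view weights: w_v = 1 / (2 ||C_v - Cstar||_F), floored at delta
update_weights <- function(Cs, Cstar, delta = 1e-8) {
  vapply(Cs, function(C) 1 / (2 * max(sqrt(sum((C - Cstar)^2)), delta)),
         numeric(1))
}
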