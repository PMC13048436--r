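#' Solver and pipeline configuration
#'
#' Collects every tunable of the model and its optimiser. Defaults follow the
#' method's stated settings where given (`knn_k = 10`, `sigma = 1`, similarity
#' exponent 2); the remaining optimiser constants are the package's own
#' documented choices.
#'
#' @param lambda1 nonnegative weight of the Gaussian-weighted distance penalty;
#'   `0` removes the term (ablation arm).
#' @param lambda2 nonnegative weight of the l2,1 noise term; `0` removes it.
#' @param knn_k neighbourhood size for the penalty weights (default 10).
#' @param sigma Gaussian bandwidth of the penalty weights (default 1).
#' @param tau_eps numeric triple (eps1, eps2, eps3) defining the information
#'   retention ratio tau = eps1 + 1/(eps2 * n + eps3), in percent.
#' @param n_clusters positive integer, or `"auto"` to choose by eigengap.
#' @param k_max largest cluster count considered by the eigengap rule.
#' @param max_iter,tolerance stopping rule of the augmented-Lagrangian loop:
#'   stop when both equality residuals fall below `tolerance` in max norm.
#' @param mu0,rho,mu_max initial penalty parameter, its growth factor, and cap.
#' @param seed integer seed driving every stochastic step (k-means restarts).
#' @param verbose logical; print per-iteration objective values.
#' @return a `run_config` list.
#' @export
solver_config <- function(lambda1 = 1, lambda2 = 1, knn_k = 10L, sigma = 1,
                          tau_eps = c(85, 0.001, 1), n_clusters = "auto",
                          k_max = 10L, max_iter = 200L, tolerance = 1e-6,
                          mu0 = 1e-3, rho = 1.5, mu_max = 1e6,
                          seed = 0L, verbose = FALSE) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, knn_k >= 1, sigma > 0,
            length(tau_eps) == 3, max_iter >= 1, tolerance > 0,
            mu0 > 0, rho >= 1, mu_max >= mu0)
  if (!identical(n_clusters, "auto")) {
    n_clusters <- as.integer(n_clusters)
    stopifnot(n_clusters >= 1)
  }
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2, knn_k = as.integer(knn_k),
         sigma = sigma, tau_eps = as.numeric(tau_eps),
         n_clusters = n_clusters, k_max = as.integer(k_max),
         max_iter = as.integer(max_iter), tolerance = tolerance,
         mu0 = mu0, rho = rho, mu_max = mu_max,
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

#' Read a configuration from a flat key = value file
#'
#' One `key = value` pair per line (TOML-style scalars; `tau_eps` as three
#' comma- or space-separated numbers); `#` starts a comment. Unknown keys are
#' an error. Values override the `solver_config()` defaults.
#'
#' @param path file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(gsub("[\"']", "", kv[2L]))
    args[[key]] <- val
  }
  known <- names(formals(solver_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  for (key in names(args)) {
    val <- args[[key]]
    args[[key]] <- switch(
      key,
      n_clusters = if (identical(val, "auto")) "auto" else as.integer(val),
      tau_eps = as.numeric(strsplit(val, "[, ]+")[[1L]]),
      verbose = as.logical(val),
      as.numeric(val)
    )
  }
  do.call(solver_config, args)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (key in names(x))
    cat(sprintf("  %-10s %s\n", key, paste(format(x[[key]]), collapse = " ")))
  invisible(x)
}
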