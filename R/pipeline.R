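#' End-to-end clustering of a paired multi-omics dataset
#'
#' Runs the full method in memory: per-view penalty graphs, the
#' augmented-Lagrangian solve, fusion `Z* = sum_v Z^v`, tau-truncation, the
#' angle-information similarity, eigengap model selection (when
#' `config$n_clusters == "auto"`), and spectral clustering.
#'
#' @param dataset a `multi_omics_dataset`.
#' @param config a `run_config`.
#' @return a `pipeline_result` list: `state` (the fitted `solver_state`),
#'   `fusion` (with `Zstar`, `Ztrunc`, `tau`, `M`, `W`), `clustering` (a
#'   `clustering_result`), `metrics` (when the dataset carries true labels),
#'   and the `config`.
#' @export
cluster_multiomics <- function(dataset, config = solver_config()) {
  state <- solve_multiomics(dataset, config)
  Zstar <- fuse_representations(state$Z)
  tau <- compute_tau(dataset$n_cells, config$tau_eps)
  Ztrunc <- simplify_affinity(Zstar, tau)
  ang <- angle_similarity(Ztrunc)
  K <- if (identical(config$n_clusters, "auto"))
    eigengap_k(ang$W, k_max = min(config$k_max, dataset$n_cells - 1L))
  else config$n_clusters
  clustering <- spectral_cluster(ang$W, K, seed = config$seed)
  metrics <- if (!is.null(dataset$labels))
    evaluate_clustering(dataset$labels, clustering$labels, embedding = ang$M)
  structure(
    list(state = state,
         fusion = list(Zstar = Zstar, Ztrunc = Ztrunc, tau = tau,
                       M = ang$M, W = ang$W),
         clustering = clustering, metrics = metrics, config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  solver: %d iteration(s), %s\n", x$state$iterations,
              if (x$state$converged) "converged" else "max_iter reached"))
  cat(sprintf("  tau = %.3f%%, clusters = %d\n", x$fusion$tau,
              x$clustering$n_clusters))
  if (!is.null(x$metrics))
    cat(sprintf("  ACC = %.4f, NMI = %.4f\n", x$metrics$acc, x$metrics$nmi))
  invisible(x)
}

#' File-based pipeline: read views, cluster, write results
#'
#' Reads the view files (and an optional true-label file), runs
#' [cluster_multiomics()], writes the predicted labels, the similarity matrix
#' `W` (Matrix Market) and a flat key-value report into `out_dir`, and returns
#' the report as a list.
#'
#' @param view_paths character vector of view file paths (see [read_view()]).
#' @param config a `run_config`.
#' @param label_path optional path to a true-label file.
#' @param out_dir output directory, created if missing.
#' @param transpose logical, recycled over views; transpose inputs stored
#'   cells x features.
#' @return a `pipeline_report` list echoing the configuration, input hashes,
#'   iteration count, final objective breakdown, chosen cluster count and
#'   eigengap spectrum head, metrics (when labels were supplied), and the
#'   written file paths.
#' @export
run_pipeline <- function(view_paths, config = solver_config(),
                         label_path = NULL, out_dir = ".",
                         transpose = FALSE) {
  transpose <- rep_len(transpose, length(view_paths))
  views <- Map(function(p, tr) read_view(p, transpose = tr),
               view_paths, transpose)
  labels <- if (!is.null(label_path)) read_labels(label_path)
  dataset <- assemble_dataset(views, labels = labels)
  res <- cluster_multiomics(dataset, config)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  label_file <- file.path(out_dir, "predicted_labels.txt")
  w_file <- file.path(out_dir, "similarity_W.mtx")
  write_labels(res$clustering$labels, label_file)
  write_view(res$fusion$W, w_file)

  last <- res$state$trace[res$state$iterations, ]
  report <- list(
    config = unclass(config),
    input_files = as.list(view_paths),
    input_md5 = as.list(unname(tools::md5sum(view_paths))),
    n_cells = dataset$n_cells, n_views = dataset$n_views,
    iterations = res$state$iterations, converged = res$state$converged,
    objective = as.list(last[c("nuclear", "penalty", "consensus",
                               "noise", "total")]),
    tau = res$fusion$tau,
    n_clusters = res$clustering$n_clusters,
    eigengap_spectrum = utils::head(res$clustering$eigenvalues, 12),
    metrics = res$metrics,
    outputs = list(labels = label_file, similarity = w_file)
  )
  report_file <- file.path(out_dir, "report.txt")
  writeLines(format_report(report), report_file)
  report$outputs$report <- report_file
  class(report) <- "pipeline_report"
  invisible(report)
}

format_report <- function(report, prefix = "") {
  out <- character(0)
  for (key in names(report)) {
    val <- report[[key]]
    if (is.list(val)) {
      out <- c(out, format_report(val, paste0(prefix, key, ".")))
    } else {
      out <- c(out, paste0(prefix, key, " = ",
                           paste(format(val, digits = 10), collapse = " ")))
    }
  }
  out
}
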