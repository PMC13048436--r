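#' Assemble a paired multi-omics dataset
#'
#' Bundles one feature matrix per omics layer (all measured on the same cells,
#' in the same order) into a validated container used by the rest of the
#' package. Matrices are stored features x cells.
#'
#' @param views list of numeric matrices, each `m_v x n` (features in rows,
#'   cells in columns). All views must have the same number of columns.
#' @param labels optional vector of length `n` with true class labels
#'   (integer or character; characters are factorised by first appearance).
#' @param cell_ids optional character vector of `n` cell identifiers. Defaults
#'   to the column names of the first view, or `cell_1..cell_n`.
#' @param feature_ids optional list of per-view feature identifier vectors.
#' @param view_names optional character vector naming the views.
#'
#' @return An object of class `multi_omics_dataset`: a list with elements
#'   `views`, `cell_ids`, `feature_ids`, `labels` (integer or `NULL`),
#'   `n_cells`, `n_views`.
#' @export
#'
#' @examples
#' x1 <- matrix(rnorm(30), nrow = 6)  # 6 features, 5 cells
#' x2 <- matrix(rnorm(20), nrow = 4)  # 4 features, same 5 cells
#' ds <- assemble_dataset(list(rna = x1, atac = x2))
#' ds$n_cells
assemble_dataset <- function(views, labels = NULL, cell_ids = NULL,
                             feature_ids = NULL, view_names = NULL) {
  if (!is.list(views) || length(views) < 1L)
    stop("`views` must be a non-empty list of matrices")
  views <- lapply(views, function(v) {
    v <- as.matrix(v)
    storage.mode(v) <- "double"
    v
  })
  ns <- vapply(views, ncol, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all views must share the same number of cells (columns); got n = ",
         paste(ns, collapse = ", "))
  n <- ns[[1L]]
  if (any(vapply(views, nrow, integer(1)) < 1L))
    stop("every view needs at least one feature row")
  bad <- which(!vapply(views, function(v) all(is.finite(v)), logical(1)))
  if (length(bad))
    stop("non-finite entries in view(s): ", paste(bad, collapse = ", "))

  if (is.null(view_names)) {
    view_names <- names(views)
    if (is.null(view_names))
      view_names <- paste0("view_", seq_along(views))
  }
  names(views) <- view_names

  if (is.null(cell_ids)) {
    cell_ids <- colnames(views[[1L]])
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  }
  if (length(cell_ids) != n)
    stop("cell_ids must have length ", n)

  if (is.null(feature_ids)) {
    feature_ids <- lapply(views, function(v) {
      ids <- rownames(v)
      if (is.null(ids)) ids <- paste0("f", seq_len(nrow(v)))
      ids
    })
  }

  if (!is.null(labels)) {
    if (length(labels) != n)
      stop("labels must have length n = ", n, ", got ", length(labels))
    labels <- factorize_labels(labels)
  }

  structure(
    list(views = views, cell_ids = as.character(cell_ids),
         feature_ids = feature_ids, labels = labels,
         n_cells = n, n_views = length(views)),
    class = "multi_omics_dataset"
  )
}

# deterministic label coding: first appearance order
factorize_labels <- function(labels) {
  as.integer(factor(as.character(labels), levels = unique(as.character(labels))))
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  cat("multi_omics_dataset:", x$n_views, "view(s),", x$n_cells, "cells\n")
  for (v in seq_along(x$views))
    cat(sprintf("  %s: %d features x %d cells\n", names(x$views)[v],
                nrow(x$views[[v]]), ncol(x$views[[v]])))
  if (!is.null(x$labels))
    cat("  labels:", length(unique(x$labels)), "classes\n")
  invisible(x)
}
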