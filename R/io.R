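#' Read a single omics view from disk
#'
#' Supports dense delimited text (comma or tab, sniffed from the first line)
#' and Matrix Market coordinate/array files. The returned matrix is oriented
#' features x cells; set `transpose = TRUE` for files stored cells x features.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.mtx` is Matrix Market, anything else
#'   dense delimited), `"dense"` or `"mtx"`.
#' @param transpose logical; transpose after reading.
#' @param header logical; does the dense file carry a header row of cell ids?
#'   Default sniffs: a first line with any non-numeric field is a header.
#' @param row_names logical; is the first dense column feature ids? Sniffed
#'   like `header`.
#' @return numeric matrix (features x cells) with finite entries.
#' @export
read_view <- function(path, format = c("auto", "dense", "mtx"),
                      transpose = FALSE, header = NULL, row_names = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  m <- if (format == "mtx") read_view_mtx(path) else
    read_view_dense(path, header = header, row_names = row_names)
  if (transpose) m <- t(m)
  if (!all(is.finite(m)))
    stop("non-finite entries (NaN/Inf/NA) in ", path)
  m
}

read_view_mtx <- function(path) {
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("failed to parse Matrix Market file ",
                                         path, ": ", conditionMessage(e)))
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
}

read_view_dense <- function(path, header = NULL, row_names = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else
    if (grepl(",", first, fixed = TRUE)) "," else " "
  fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x))) |
    toupper(x) %in% c("NA", "NAN", "INF", "-INF")
  if (is.null(header)) header <- !all(is_num(fields))
  dt <- data.table::fread(path, sep = sep, header = header,
                          data.table = FALSE, showProgress = FALSE)
  if (is.null(row_names)) row_names <- !all(vapply(dt[[1L]], is_num, logical(1)))
  rn <- NULL
  if (row_names) {
    rn <- as.character(dt[[1L]])
    dt <- dt[, -1L, drop = FALSE]
  }
  non_num <- which(!vapply(dt, is.numeric, logical(1)))
  if (length(non_num))
    stop("non-numeric column(s) ", paste(non_num, collapse = ", "),
         " in ", path)
  m <- as.matrix(dt)
  if (!is.null(rn)) rownames(m) <- rn
  if (!header) colnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Write a view matrix to disk
#'
#' @param m numeric matrix (features x cells).
#' @param path destination; a `.mtx` extension selects Matrix Market, anything
#'   else tab-delimited dense text.
#' @param format `"auto"`, `"dense"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_view <- function(m, path, format = c("auto", "dense", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
  } else {
    data.table::fwrite(as.data.frame(m), path, sep = "\t",
                       col.names = !is.null(colnames(m)))
  }
  invisible(path)
}

#' Read / write a label file (one label per line, in cell order)
#'
#' String labels are factorised deterministically by first appearance.
#'
#' @param path file path.
#' @return integer vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x)]
  factorize_labels(x)
}

#' @rdname read_labels
#' @param labels vector of labels to write.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}
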