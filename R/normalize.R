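#' Optional per-view preprocessing
#'
#' The solver consumes matrices as given; none of these transforms is applied
#' automatically to user data. They are offered because the model's default
#' Gaussian bandwidth (`sigma = 1`) and unit regularisation weights assume
#' inter-cell distances of order 1, which raw count matrices do not have.
#'
#' * `"l2"` — scale each cell (column) to unit l2 norm.
#' * `"libsize"` — scale each cell to unit total (library-size normalisation).
#' * `"log1p"` — elementwise `log(1 + x)`.
#'
#' @param X numeric matrix, features x cells.
#' @param method one of `"l2"`, `"libsize"`, `"log1p"`.
#' @return transformed matrix of the same shape.
#' @export
normalize_view <- function(X, method = c("l2", "libsize", "log1p")) {
  method <- match.arg(method)
  switch(method,
         l2 = sweep(X, 2, pmax(sqrt(colSums(X^2)), .Machine$double.eps), "/"),
         libsize = sweep(X, 2, pmax(colSums(abs(X)), .Machine$double.eps), "/"),
         log1p = log1p(X))
}
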