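#' Standardize predictors and center the response
#'
#' Scales every gene row to mean 0 and unit sum of squares
#' (\eqn{\sum_i x_{ij} = 0}, \eqn{\sum_i x_{ij}^2 = 1}) and centers the
#' response, the normalization under which the penalized regression is
#' defined. A zero-variance gene is a hard error (filter first); the
#' \code{standardized} flag in \code{metadata} is set.
#'
#' @param se a \code{SummarizedExperiment} whose \code{colData} carries
#'   \code{group} (and optionally \code{response}, which is re-centered).
#' @return the standardized \code{SummarizedExperiment}.
#' @export
standardizeExpression <- function(se) {
  m <- SummarizedExperiment::assay(se, "exprs")
  ctr <- m - rowMeans(m)
  ss <- rowSums(ctr^2)
  if (any(ss == 0)) {
    stop("zero-variance gene(s): ",
         paste(rownames(m)[ss == 0], collapse = ", "))
  }
  m <- ctr / sqrt(ss)
  SummarizedExperiment::assay(se, "exprs") <- m
  cd <- SummarizedExperiment::colData(se)
  resp <- cd$response
  if (is.null(resp)) {
    if (is.null(cd$group)) stop("colData needs `group` or `response`")
    resp <- as.numeric(cd$group)
  }
  SummarizedExperiment::colData(se)$response <- resp - mean(resp)
  S4Vectors::metadata(se)$standardized <- TRUE
  se
}
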