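#' Normalized graph Laplacian over a gene set
#'
#' Builds the normalized Laplacian of the network restricted to
#' \code{geneIds}: only edges with both endpoints in the set contribute.
#' With weighted degree \eqn{d_v = \sum_{u \sim v} w(u, v)},
#' \deqn{L_{uv} = 1 \textrm{ if } u = v, d_u \neq 0;\quad
#'       -w(u,v)/\sqrt{d_u d_v} \textrm{ if } u \sim v;\quad
#'       0 \textrm{ otherwise},}
#' i.e. \eqn{I - D^{-1/2} W D^{-1/2}} on non-isolated nodes. The row and
#' column of a gene that is isolated (or absent from the network) are all
#' zero, so such genes feel a pure L1 penalty in the regression.
#'
#' The result is symmetric and positive semi-definite with eigenvalues in
#' [0, 2].
#'
#' @param net a [GeneNetwork-class].
#' @param geneIds genes (rows/columns) of the Laplacian, in order.
#' @return a symmetric numeric matrix with dimnames \code{geneIds}.
#' @examples
#' tri <- GeneNetwork(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
#' buildLaplacian(tri, c("A", "B", "C"))
#' @export
buildLaplacian <- function(net, geneIds) {
  geneIds <- as.character(geneIds)
  stopifnot(!anyDuplicated(geneIds))
  p <- length(geneIds)
  L <- matrix(0, p, p, dimnames = list(geneIds, geneIds))
  ed <- networkEdges(net)
  ed <- ed[ed$a %in% geneIds & ed$b %in% geneIds, , drop = FALSE]
  if (nrow(ed)) {
    d <- stats::setNames(rep(0, p), geneIds)
    agg <- tapply(c(ed$weight, ed$weight), c(ed$a, ed$b), sum)
    d[names(agg)] <- agg
    ia <- match(ed$a, geneIds)
    ib <- match(ed$b, geneIds)
    off <- -ed$weight / sqrt(d[ed$a] * d[ed$b])
    L[cbind(ia, ib)] <- off
    L[cbind(ib, ia)] <- off
    diag(L)[d > 0] <- 1
  }
  L
}

## Internal sanity checks used by the test-suite: symmetry, diagonal range,
## spectrum within [0, 2].
validateLaplacian <- function(L, tol = 1e-8) {
  stopifnot(isSymmetric(L, tol = tol))
  stopifnot(all(diag(L) >= -tol & diag(L) <= 1 + tol))
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(all(ev >= -tol & ev <= 2 + tol))
  invisible(TRUE)
}
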