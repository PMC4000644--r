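#' Weight an interaction graph by expression correlation
#'
#' Sets every PPI edge weight to the Pearson correlation of the two genes'
#' expression vectors (its absolute value by default, so strongly
#' anti-correlated pairs are equally attractive to the extraction step;
#' \code{signed = TRUE} keeps raw r for audit). Edges with an unmeasured
#' endpoint, or one whose expression has zero variance, get weight 0: they
#' remain selectable for connectivity at pure penalty cost. Correlation is
#' scale-invariant, so raw or standardized expression gives the same
#' weights.
#'
#' Gene-to-protein identifier matching is case-insensitive symbol equality;
#' fixed genes not present in the graph are dropped with a warning listing
#' them.
#'
#' @param ppi a [GeneNetwork-class] of protein interactions.
#' @param se a \code{SummarizedExperiment} of expression values.
#' @param start,end anchor protein identifiers.
#' @param fixedNodes genes pinned into any solution (typically
#'   \code{selectedGenes()} of the regression fit).
#' @param signed keep signed correlations instead of magnitudes.
#' @return a [WeightedPPIGraph-class].
#' @export
computeEdgeWeights <- function(ppi, se, start, end,
                               fixedNodes = character(), signed = FALSE) {
  ed <- networkEdges(ppi)
  m <- SummarizedExperiment::assay(se, "exprs")
  lookup <- stats::setNames(seq_len(nrow(m)), tolower(rownames(m)))
  ia <- lookup[tolower(ed$a)]
  ib <- lookup[tolower(ed$b)]
  w <- numeric(nrow(ed))
  zeroVar <- 0L
  for (k in seq_len(nrow(ed))) {
    if (is.na(ia[k]) || is.na(ib[k])) next       # unmeasured endpoint -> 0
    x <- m[ia[k], ]
    y <- m[ib[k], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      zeroVar <- zeroVar + 1L
      next
    }
    w[k] <- stats::cor(x, y)
  }
  if (zeroVar > 0L) {
    warning(zeroVar, " edge(s) set to weight 0: zero-variance gene")
  }
  if (!signed) w <- abs(w)
  w <- pmin(pmax(w, if (signed) -1 else 0), 1)
  nodes <- networkNodes(ppi)
  mapId <- function(id) {
    hit <- nodes[match(tolower(id), tolower(nodes))]
    if (is.na(hit)) id else hit
  }
  start <- mapId(start)
  end <- mapId(end)
  fixedMapped <- vapply(fixedNodes, mapId, "")
  missingFixed <- fixedMapped[!fixedMapped %in% nodes]
  if (length(missingFixed)) {
    warning("fixed gene(s) absent from the PPI graph, dropped: ",
            paste(missingFixed, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(a = ed$a, b = ed$b, weight = w, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  new("WeightedPPIGraph", graph = g, start = start, end = end,
      fixedNodes = unname(fixedMapped[fixedMapped %in% nodes]))
}
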