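#' Build a gene network from an edge table
#'
#' Constructs a simple weighted undirected graph over gene identifiers.
#' Self-loops are discarded and duplicate edges (in either orientation) are
#' collapsed keeping the maximum weight; these are the same normalization
#' rules the edge-list reader applies.
#'
#' @param edges a data frame whose first two columns are the endpoint gene
#'   ids and whose optional third column is a nonnegative weight (default 1).
#' @param nodes additional isolated nodes to include beyond the endpoints.
#' @return a [GeneNetwork-class] object.
#' @examples
#' net <- GeneNetwork(data.frame(a = c("A", "B"), b = c("B", "C")))
#' networkEdges(net)
#' @export
GeneNetwork <- function(edges = NULL, nodes = character()) {
  if (is.null(edges) || nrow(edges) == 0L) {
    ed <- canonicalEdges(character(), character())
  } else {
    w <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else NULL
    if (!is.null(w) && anyNA(w)) {
      stop("malformed numeric weight in edge table", call. = FALSE)
    }
    if (!is.null(w) && any(w < 0)) {
      stop("negative edge weights are not allowed", call. = FALSE)
    }
    ed <- canonicalEdges(edges[[1L]], edges[[2L]], w)
  }
  allNodes <- sort(unique(c(ed$a, ed$b, as.character(nodes))))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = allNodes)
  new("GeneNetwork", graph = g)
}

#' @describeIn GeneNetwork node identifiers, sorted.
#' @param x a \code{GeneNetwork}.
#' @export
setMethod("networkNodes", "GeneNetwork", function(x) {
  sort(igraph::V(x@graph)$name)
})

#' @describeIn GeneNetwork canonical edge table with columns
#'   \code{a}, \code{b}, \code{weight}.
#' @export
setMethod("networkEdges", "GeneNetwork", function(x) {
  el <- igraph::as_edgelist(x@graph, names = TRUE)
  w <- igraph::edge_attr(x@graph, "weight")
  if (is.null(w)) w <- rep(1, nrow(el))
  canonicalEdges(el[, 1L], el[, 2L], w)
})

#' @describeIn GeneNetwork the underlying \pkg{igraph} object.
#' @export
setMethod("networkGraph", "GeneNetwork", function(x) x@graph)

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("%s with %d nodes and %d edges\n", class(object),
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
})

setMethod("show", "WeightedPPIGraph", function(object) {
  cat(sprintf(paste0("WeightedPPIGraph: %d nodes, %d edges; ",
                     "start=%s end=%s; %d fixed nodes\n"),
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              object@start, object@end, length(object@fixedNodes)))
})
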