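#' @import methods
#' @importFrom igraph V E ecount vcount as_edgelist edge_attr is_simple
#'   which_loop graph_from_data_frame simplify degree components
NULL

setOldClass("igraph")

#' Weighted undirected gene network
#'
#' Thin S4 wrapper around an \pkg{igraph} graph. Nodes are gene (protein)
#' symbols; edges are undirected, simple (no self-loops, no duplicates) and
#' carry a nonnegative weight (1 when the source had no weight column).
#'
#' @slot graph an undirected simple \pkg{igraph} graph with a \code{weight}
#'   edge attribute.
#'
#' @seealso [GeneNetwork()], [networkNodes()], [networkEdges()]
#' @export
setClass("GeneNetwork", representation(graph = "igraph"))

setValidity("GeneNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops are not allowed")
  if (!igraph::is_simple(g)) msg <- c(msg, "duplicate edges are not allowed")
  w <- igraph::edge_attr(g, "weight")
  if (igraph::ecount(g) > 0 && (is.null(w) || anyNA(w))) {
    msg <- c(msg, "every edge needs a numeric weight")
  }
  if (length(msg)) msg else TRUE
})

#' Correlation-weighted interaction graph with anchors
#'
#' A [GeneNetwork-class] whose edge weights come from expression
#' correlations, plus the two anchor proteins of the signal transduction
#' network (STN) and the set of nodes fixed into any solution (the
#' regression-selected genes).
#'
#' @slot start,end anchor protein identifiers (start and end of the STN).
#' @slot fixedNodes nodes whose membership indicator is pinned to 1.
#'
#' @export
setClass("WeightedPPIGraph", contains = "GeneNetwork",
         representation(start = "character", end = "character",
                        fixedNodes = "character"))

setValidity("WeightedPPIGraph", function(object) {
  nodes <- igraph::V(object@graph)$name
  msg <- character()
  if (length(object@start) != 1L || length(object@end) != 1L) {
    msg <- c(msg, "start and end must be single identifiers")
  } else {
    if (identical(object@start, object@end)) {
      msg <- c(msg, "start and end must differ")
    }
    if (!all(c(object@start, object@end) %in% nodes)) {
      msg <- c(msg, "start and end must be nodes of the graph")
    }
  }
  if (!all(object@fixedNodes %in% nodes)) {
    msg <- c(msg, "fixedNodes must be nodes of the graph")
  }
  w <- igraph::edge_attr(object@graph, "weight")
  if (length(w) && (min(w) < -1 - 1e-12 || max(w) > 1 + 1e-12)) {
    msg <- c(msg, "correlation weights must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic study configuration
#'
#' Parameters of the synthetic ground-truth generator. Defaults emulate a
#' small-n / large-p four-group microarray study: 4 ordinal phenotype groups
#' of \code{nPerGroup} samples each, \code{nGenes} genes of which
#' \code{nSupport} carry a group-dependent mean shift of
#' \code{effectSize * group * noiseSd}, and a planted start-to-end path of
#' \code{pathLength} intermediate nodes whose genes share a latent factor
#' with loading \code{pathCorrelation} (pairwise Pearson correlation
#' \code{pathCorrelation^2}).
#'
#' @slot nPerGroup samples per phenotype group (4 groups).
#' @slot nGenes,nSupport total genes and size of the true regression support.
#' @slot effectSize per-group-step mean shift, in units of \code{noiseSd}.
#' @slot pathLength number of intermediate nodes on the planted path.
#' @slot pathCorrelation latent-factor loading in (0, 1] for path genes.
#' @slot noiseSd residual standard deviation.
#' @slot networkModel background graph model, \code{"preferential-attachment"}
#'   or \code{"erdos-renyi"}.
#' @slot attachmentEdges,edgeProb model parameter (edges per new node, or
#'   edge probability).
#' @slot seed integer seed; all outputs are pure functions of (config, seed).
#'
#' @export
setClass("SimulationConfig",
         representation(nPerGroup = "integer", nGenes = "integer",
                        nSupport = "integer", effectSize = "numeric",
                        pathLength = "integer", pathCorrelation = "numeric",
                        noiseSd = "numeric", networkModel = "character",
                        attachmentEdges = "integer", edgeProb = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  if (object@nGenes < 2L) msg <- c(msg, "nGenes must be >= 2")
  if (object@nSupport >= object@nGenes) {
    msg <- c(msg, "nSupport must be < nGenes")
  }
  if (object@nSupport < 0L) msg <- c(msg, "nSupport must be >= 0")
  if (object@pathLength < 0L) msg <- c(msg, "pathLength must be >= 0")
  if (object@pathLength + 2L > object@nGenes) {
    msg <- c(msg, "pathLength + 2 must be <= nGenes")
  }
  if (object@nSupport + object@pathLength + 2L > object@nGenes) {
    msg <- c(msg, "need nSupport + pathLength + 2 <= nGenes (disjoint plantings)")
  }
  if (!(object@pathCorrelation > 0 && object@pathCorrelation <= 1)) {
    msg <- c(msg, "pathCorrelation must lie in (0, 1]")
  }
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (!object@networkModel %in% c("preferential-attachment", "erdos-renyi")) {
    msg <- c(msg, "unknown networkModel")
  }
  if (object@networkModel == "preferential-attachment" &&
      (object@attachmentEdges < 1L ||
       object@attachmentEdges >= object@nGenes)) {
    msg <- c(msg, "attachmentEdges must satisfy 1 <= m < nGenes")
  }
  if (object@networkModel == "erdos-renyi" &&
      (is.na(object@edgeProb) || object@edgeProb < 0 || object@edgeProb > 1)) {
    msg <- c(msg, "edgeProb must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Planted ground truth of a synthetic study
#'
#' @slot supportGenes genes with nonzero planted coefficient.
#' @slot plantedPath ordered node sequence from the start to the end anchor.
#' @slot plantedEdges canonical edge table of that path (guaranteed to be
#'   present in the emitted graph).
#' @slot betaTrue named numeric vector of planted coefficients; its nonzero
#'   names equal \code{supportGenes}.
#' @slot start,end the anchor identifiers.
#'
#' @export
setClass("SyntheticTruth",
         representation(supportGenes = "character", plantedPath = "character",
                        plantedEdges = "data.frame", betaTrue = "numeric",
                        start = "character", end = "character"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  nz <- names(object@betaTrue)[abs(object@betaTrue) > 0]
  if (!setequal(nz, object@supportGenes)) {
    msg <- c(msg, "supportGenes must equal the nonzero names of betaTrue")
  }
  k <- length(object@plantedPath)
  if (k < 2L || object@plantedPath[1L] != object@start ||
      object@plantedPath[k] != object@end) {
    msg <- c(msg, "plantedPath must run from start to end")
  }
  if (length(msg)) msg else TRUE
})

#' Cross-validation grid for the penalized regression
#'
#' @slot lambda1 ascending positive values of the L1 penalty.
#' @slot lambda2 ascending nonnegative values of the Laplacian penalty.
#' @slot nFolds number of CV folds (default 10).
#' @slot cvSeed seed for the fold shuffle.
#'
#' @export
setClass("PenaltyGrid",
         representation(lambda1 = "numeric", lambda2 = "numeric",
                        nFolds = "integer", cvSeed = "integer"))

setValidity("PenaltyGrid", function(object) {
  msg <- character()
  if (!length(object@lambda1) || any(object@lambda1 <= 0)) {
    msg <- c(msg, "lambda1 values must be positive and nonempty")
  }
  if (!length(object@lambda2) || any(object@lambda2 < 0)) {
    msg <- c(msg, "lambda2 values must be nonnegative and nonempty")
  }
  if (is.unsorted(object@lambda1) || is.unsorted(object@lambda2)) {
    msg <- c(msg, "grids must be sorted ascending")
  }
  if (object@nFolds < 2L) msg <- c(msg, "nFolds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Fitted network-constrained regression
#'
#' @slot beta named coefficient vector over the fitted gene set.
#' @slot lambda1,lambda2 tuned penalties.
#' @slot cvError mean held-out squared prediction error at the chosen point.
#' @slot cvTable full CV table (lambda1, lambda2, cv_error).
#' @slot objective penalized criterion at the optimum.
#' @slot sweeps coordinate-descent sweeps used by the final fit.
#'
#' @export
setClass("SelectionResult",
         representation(beta = "numeric", lambda1 = "numeric",
                        lambda2 = "numeric", cvError = "numeric",
                        cvTable = "data.frame", objective = "numeric",
                        sweeps = "numeric"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (is.null(names(object@beta))) msg <- c(msg, "beta must be named")
  if (length(object@cvError) && object@cvError < 0) {
    msg <- c(msg, "cvError must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Binary program for subnetwork extraction
#'
#' One binary indicator per canonical (unordered) edge and per node. The
#' objective is \eqn{S = -\sum w_{ij} y_{ij} + \lambda \sum y_{ij}};
#' constraints couple edges to endpoints (\eqn{y_{ij} \le x_i, x_j}), force
#' degree \eqn{\ge 1} at the anchors, degree \eqn{\ge 2 x_i} at every other
#' node, and pin the fixed nodes to \eqn{x_i = 1}.
#'
#' @slot edges canonical edge table (a, b, weight), sorted lexicographically;
#'   this ordering defines the deterministic tie-break among optima.
#' @slot nodes node identifiers.
#' @slot start,end anchor identifiers.
#' @slot fixedNodes nodes with \eqn{x_i} pinned to 1.
#' @slot lambda positive per-edge penalty.
#'
#' @export
setClass("ILPInstance",
         representation(edges = "data.frame", nodes = "character",
                        start = "character", end = "character",
                        fixedNodes = "character", lambda = "numeric"))

setValidity("ILPInstance", function(object) {
  msg <- character()
  if (length(object@lambda) != 1L || object@lambda <= 0) {
    msg <- c(msg, "lambda must be a single positive value")
  }
  ep <- unique(c(object@edges$a, object@edges$b))
  if (!all(ep %in% object@nodes)) {
    msg <- c(msg, "edge endpoints must be listed in nodes")
  }
  if (!all(c(object@start, object@end, object@fixedNodes) %in% object@nodes)) {
    msg <- c(msg, "anchors and fixed nodes must be listed in nodes")
  }
  if (length(msg)) msg else TRUE
})

#' Optimal subnetwork returned by the exact solver
#'
#' @slot selectedEdges edge table (a, b, weight) of the optimum.
#' @slot selectedNodes endpoints of selected edges plus the fixed nodes.
#' @slot objective value of the minimized criterion, recomputed from the
#'   assignment.
#' @slot components connected components of the selected subgraph, largest
#'   first.
#' @slot provenOptimal TRUE iff optimality was proven (always, for this
#'   exact solver; kept explicit so heuristic results can never pass
#'   silently).
#' @slot start,end,fixedNodes copied from the instance, for role labelling.
#'
#' @export
setClass("PathwaySolution",
         representation(selectedEdges = "data.frame",
                        selectedNodes = "character", objective = "numeric",
                        components = "list", provenOptimal = "logical",
                        start = "character", end = "character",
                        fixedNodes = "character"))

setValidity("PathwaySolution", function(object) {
  msg <- character()
  ep <- unique(c(object@selectedEdges$a, object@selectedEdges$b))
  if (!all(ep %in% object@selectedNodes)) {
    msg <- c(msg, "endpoints of selected edges must be selected nodes")
  }
  if (length(msg)) msg else TRUE
})
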