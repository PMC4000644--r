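#' Build the subnetwork-extraction binary program
#'
#' Canonicalizes the weighted graph into one binary variable per unordered
#' edge (the symmetric double sum of the criterion is counted once per
#' edge; weights and the penalty are interpreted on that single-count
#' scale) and records the constraint data: edge-endpoint coupling, degree
#' \eqn{\ge 1} at the two anchors, degree \eqn{\ge 2 x_i} elsewhere, and
#' \eqn{x_i = 1} for the fixed (known-member) nodes. An anchor with no
#' incident edge, or a fixed node with graph degree below 2, is reported
#' as infeasible before any solving.
#'
#' @param graph a [WeightedPPIGraph-class].
#' @param lambdaPenalty positive per-edge penalty \eqn{\lambda} controlling
#'   network size (larger values give smaller networks).
#' @return an [ILPInstance-class].
#' @export
buildILP <- function(graph, lambdaPenalty) {
  stopifnot(is(graph, "WeightedPPIGraph"))
  validObject(graph)
  if (length(lambdaPenalty) != 1L || lambdaPenalty <= 0) {
    stop("lambdaPenalty must be a single positive value")
  }
  ed <- networkEdges(graph)
  nodes <- networkNodes(graph)
  inst <- new("ILPInstance", edges = ed, nodes = nodes,
              start = graph@start, end = graph@end,
              fixedNodes = unique(graph@fixedNodes),
              lambda = as.numeric(lambdaPenalty))
  preCheckInstance(inst)
  inst
}

## Structural infeasibility visible from the graph alone: an anchor that is
## isolated (its ">= 1" constraint cannot hold) or a fixed non-anchor node
## with graph degree < 2 (its ">= 2 x_i" constraint cannot hold).
preCheckInstance <- function(instance) {
  deg <- stats::setNames(rep(0L, length(instance@nodes)), instance@nodes)
  tab <- table(c(instance@edges$a, instance@edges$b))
  deg[names(tab)] <- as.integer(tab)
  anchors <- c(instance@start, instance@end)
  bad <- c(anchors[deg[anchors] < 1L],
           setdiff(instance@fixedNodes, anchors)[
             deg[setdiff(instance@fixedNodes, anchors)] < 2L])
  if (length(bad)) {
    stop(infeasibleError(
      paste0("infeasible instance: node(s) ", paste(bad, collapse = ", "),
             " cannot meet their degree requirement"), bad))
  }
  invisible(TRUE)
}

## Independent feasibility check of an edge assignment, written directly
## from the constraint definitions (shared by the solver's final
## verification and the enumeration oracle).
checkAssignment <- function(instance, sel) {
  ed <- instance@edges[sel, , drop = FALSE]
  deg <- stats::setNames(rep(0L, length(instance@nodes)), instance@nodes)
  tab <- table(c(ed$a, ed$b))
  deg[names(tab)] <- as.integer(tab)
  anchors <- c(instance@start, instance@end)
  fixed <- setdiff(instance@fixedNodes, anchors)
  other <- setdiff(instance@nodes, c(anchors, fixed))
  all(deg[anchors] >= 1L) && all(deg[fixed] >= 2L) &&
    !any(deg[other] == 1L)
}

## TRUE if logical vector a precedes b in the lexicographic order with
## FALSE < TRUE; the shared tie-break among optimal assignments.
lexLess <- function(a, b) {
  i <- which(a != b)
  length(i) > 0L && !a[i[1L]]
}

makeSolution <- function(instance, sel, objective) {
  ed <- instance@edges[sel, , drop = FALSE]
  rownames(ed) <- NULL
  nodes <- sort(unique(c(ed$a, ed$b, instance@fixedNodes)))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
  cmp <- igraph::components(g)
  comps <- split(names(cmp$membership), cmp$membership)
  comps <- comps[order(-lengths(comps),
                       vapply(comps, min, ""))]
  names(comps) <- NULL
  comps <- lapply(comps, sort)
  new("PathwaySolution", selectedEdges = ed, selectedNodes = nodes,
      objective = objective, components = comps, provenOptimal = TRUE,
      start = instance@start, end = instance@end,
      fixedNodes = instance@fixedNodes)
}

#' Solve the binary program exactly
#'
#' Depth-first branch-and-bound over the edge variables. Branching is
#' dynamic: while any node is short of its degree requirement, its
#' cheapest undecided incident edge is branched (inclusion first);
#' otherwise the cheapest undecided objective-lowering edge
#' (\eqn{\lambda - w < 0}) is branched; when neither exists, excluding
#' every remaining edge completes an optimal (and lexicographically
#' minimal) extension of the current partial assignment. The lower bound
#' adds, to the cost of the decided prefix, every undecided
#' objective-lowering edge plus a repair term: each deficient node is
#' charged its missing incident edges at the cheapest qualifying
#' nonnegative costs — at full cost when the edge's other endpoint is not
#' deficient, at half cost when it is (it may then serve both ends). A
#' node whose remaining incident edges cannot meet its requirement prunes
#' the branch. Among optimal assignments the lexicographically smallest
#' edge-indicator vector in canonical edge order (excluding
#' earlier-ordered edges preferred) is returned, the same tie-break as
#' [bruteForceOracle()]. The
#' returned objective is recomputed independently from the assignment and
#' the assignment is re-checked against every constraint; optimality is
#' always proven (there is no heuristic or time-limited mode).
#'
#' @param instance an [ILPInstance-class].
#' @param nodeLimit search-node budget; exceeding it is an error, never a
#'   silently suboptimal result.
#' @return a [PathwaySolution-class].
#' @examples
#' wg <- new("WeightedPPIGraph",
#'           graph = igraph::graph_from_data_frame(
#'             data.frame(a = "S", b = "E", weight = 0.9), FALSE),
#'           start = "S", end = "E", fixedNodes = character())
#' solveILP(buildILP(wg, 0.65))@objective   # -0.9 + 0.65
#' @export
solveILP <- function(instance, nodeLimit = 5e6) {
  stopifnot(is(instance, "ILPInstance"))
  validObject(instance)
  preCheckInstance(instance)
  ed <- instance@edges
  m <- nrow(ed)
  nodes <- instance@nodes
  V <- length(nodes)
  ia <- match(ed$a, nodes)
  ib <- match(ed$b, nodes)
  cost <- instance@lambda - ed$weight
  isAnchor <- nodes %in% c(instance@start, instance@end)
  isFixed <- nodes %in% instance@fixedNodes & !isAnchor
  incList <- lapply(seq_len(V), function(v) which(ia == v | ib == v))
  state <- integer(m)                      # 0 undecided, 1 in, -1 out
  selDeg <- integer(V)
  best <- Inf
  bestSel <- NULL
  visited <- 0L
  eps <- 1e-9

  deficiency <- function() {
    req <- ifelse(isAnchor, 1L, ifelse(isFixed | selDeg > 0L, 2L, 0L))
    pmax(req - selDeg, 0L)
  }
  ## lower bound on the objective of any feasible completion of `state`
  bound <- function(cur) {
    und <- state == 0L
    b <- cur + sum(cost[und & cost < 0])
    defic <- deficiency()
    deficNode <- defic > 0L
    extra <- 0
    for (v in which(deficNode)) {
      ie <- incList[[v]]
      ie <- ie[und[ie]]
      if (length(ie) < defic[v]) return(Inf)   # requirement unreachable
      cc <- cost[ie]
      need <- defic[v] - sum(cc < 0)
      if (need > 0L) {
        nonneg <- cc >= 0
        partnerDefic <- deficNode[ia[ie] + ib[ie] - v][nonneg]
        charge <- cc[nonneg] * ifelse(partnerDefic, 0.5, 1)
        extra <- extra + sum(sort(charge)[seq_len(need)])
      }
    }
    b + extra
  }
  commit <- function(cur) {
    sel <- state == 1L
    if (cur < best - eps ||
        (cur <= best + eps &&
         (is.null(bestSel) || lexLess(sel, bestSel)))) {
      best <<- min(best, cur)
      bestSel <<- sel
    }
  }
  recurse <- function(cur) {
    visited <<- visited + 1L
    if (visited > nodeLimit) {
      stop("branch-and-bound node limit exceeded; optimality not proven")
    }
    ## next decision: serve a deficient node, else take an attractive edge
    defic <- deficiency()
    e <- NA_integer_
    dv <- which(defic > 0L)
    if (length(dv)) {
      v <- dv[1L]
      ie <- incList[[v]]
      ie <- ie[state[ie] == 0L]
      if (!length(ie)) return(invisible())     # cannot be repaired
      e <- ie[which.min(cost[ie])]
    } else {
      negs <- which(state == 0L & cost < 0)
      if (length(negs)) {
        e <- negs[which.min(cost[negs])]
      } else {
        commit(cur)          # excluding the rest is optimal and lex-minimal
        return(invisible())
      }
    }
    va <- ia[e]
    vb <- ib[e]
    for (take in c(TRUE, FALSE)) {
      if (take) {
        state[e] <<- 1L
        selDeg[va] <<- selDeg[va] + 1L
        selDeg[vb] <<- selDeg[vb] + 1L
        newCur <- cur + cost[e]
      } else {
        state[e] <<- -1L
        newCur <- cur
      }
      if (bound(newCur) <= best + eps) recurse(newCur)
      if (take) {
        selDeg[va] <<- selDeg[va] - 1L
        selDeg[vb] <<- selDeg[vb] - 1L
      }
      state[e] <<- 0L
    }
    invisible()
  }
  recurse(0)
  if (is.null(bestSel)) {
    stop(infeasibleError(paste0(
      "infeasible instance: no edge assignment satisfies the anchor and ",
      "degree constraints (anchors ", instance@start, ", ", instance@end,
      ")"), c(instance@start, instance@end)))
  }
  objective <- -sum(ed$weight[bestSel]) +
    instance@lambda * sum(bestSel)          # recomputed from the assignment
  stopifnot(abs(objective - best) <= 1e-9)
  if (!checkAssignment(instance, bestSel)) {
    stop("internal error: solver returned an infeasible assignment")
  }
  makeSolution(instance, bestSel, objective)
}

#' Exhaustive-enumeration oracle
#'
#' Enumerates all \eqn{2^{|E|}} edge subsets, derives node indicators as
#' endpoint unions plus the fixed nodes, filters by every constraint and
#' returns the minimum-objective subset under the same lexicographic
#' tie-break as [solveILP()]. The definitional reference implementation the
#' solver is validated against; refuses instances with more than 20 edges.
#'
#' @param instance an [ILPInstance-class].
#' @return a [PathwaySolution-class].
#' @export
bruteForceOracle <- function(instance) {
  stopifnot(is(instance, "ILPInstance"))
  preCheckInstance(instance)
  ed <- instance@edges
  m <- nrow(ed)
  if (m > 20L) stop("oracle limited to instances with <= 20 edges")
  nodes <- instance@nodes
  V <- length(nodes)
  ia <- match(ed$a, nodes)
  ib <- match(ed$b, nodes)
  subsets <- 0:(2^m - 1)
  M <- vapply(seq_len(m),
              function(j) bitwAnd(subsets, bitwShiftL(1L, j - 1L)) != 0L,
              logical(length(subsets)))
  if (length(subsets) == 1L) M <- matrix(M, nrow = 1L)
  inc <- matrix(0, m, V)
  inc[cbind(seq_len(m), ia)] <- 1
  inc[cbind(seq_len(m), ib)] <- 1
  deg <- M %*% inc
  isAnchor <- nodes %in% c(instance@start, instance@end)
  isFixed <- nodes %in% instance@fixedNodes & !isAnchor
  feas <- rowSums(deg[, isAnchor, drop = FALSE] < 1) == 0 &
    rowSums(deg[, isFixed, drop = FALSE] < 2) == 0 &
    rowSums(deg[, !isAnchor & !isFixed, drop = FALSE] == 1) == 0
  if (!any(feas)) {
    stop(infeasibleError(paste0(
      "infeasible instance: no edge assignment satisfies the anchor and ",
      "degree constraints (anchors ", instance@start, ", ", instance@end,
      ")"), c(instance@start, instance@end)))
  }
  obj <- drop(M %*% (instance@lambda - ed$weight))
  minObj <- min(obj[feas])
  cand <- which(feas & obj <= minObj + 1e-9)
  Mc <- M[cand, , drop = FALSE]
  pick <- cand[do.call(order, as.data.frame(Mc))[1L]]
  sel <- M[pick, ]
  objective <- -sum(ed$weight[sel]) + instance@lambda * sum(sel)
  makeSolution(instance, sel, objective)
}

#' Sweep the size-control penalty
#'
#' Solves the program once per \eqn{\lambda} value and tabulates the
#' selected-edge count and objective — the basis for choosing a penalty by
#' target network size. Because each selected edge contributes
#' \eqn{\lambda - w} to the objective, larger penalties give smaller
#' networks (the edge count is non-increasing in \eqn{\lambda}).
#'
#' @param graph a [WeightedPPIGraph-class].
#' @param lambdas ascending positive penalty values.
#' @return a data frame with columns \code{lambda}, \code{n_edges},
#'   \code{objective}.
#' @export
sweepLambda <- function(graph, lambdas) {
  stopifnot(all(lambdas > 0), !is.unsorted(lambdas))
  rows <- lapply(lambdas, function(lam) {
    sol <- solveILP(buildILP(graph, lam))
    data.frame(lambda = lam, n_edges = nrow(sol@selectedEdges),
               objective = sol@objective)
  })
  do.call(rbind, rows)
}

#' Component report for a solved pathway
#'
#' Connected components of the selected subgraph (the degree constraints
#' admit several disjoint pieces, reported as-is rather than patched with
#' extra connectivity constraints), with a per-node role label for network
#' export and a flag for whether the two anchors landed in one component.
#'
#' @param solution a [PathwaySolution-class].
#' @return a list with \code{report} (data frame: node, component, role,
#'   degree), \code{components} (list of node vectors, largest first) and
#'   \code{anchorsConnected}.
#' @export
extractComponents <- function(solution) {
  stopifnot(is(solution, "PathwaySolution"))
  roles <- nodeRoles(solution)
  comps <- solution@components
  compId <- stats::setNames(rep(seq_along(comps), lengths(comps)),
                            unlist(comps))
  deg <- stats::setNames(rep(0L, length(solution@selectedNodes)),
                         solution@selectedNodes)
  tab <- table(c(solution@selectedEdges$a, solution@selectedEdges$b))
  deg[names(tab)] <- as.integer(tab)
  nodes <- names(compId)
  report <- data.frame(node = nodes,
                       component = unname(compId),
                       role = unname(roles[nodes]),
                       degree = unname(deg[nodes]),
                       stringsAsFactors = FALSE)
  report <- report[order(report$component, report$node), ]
  rownames(report) <- NULL
  list(report = report, components = comps,
       anchorsConnected = compId[[solution@start]] ==
         compId[[solution@end]])
}

setMethod("show", "ILPInstance", function(object) {
  cat(sprintf(paste0("ILPInstance: %d edge and %d node variables; ",
                     "lambda=%.3g; anchors %s -> %s; %d fixed\n"),
              nrow(object@edges), length(object@nodes), object@lambda,
              object@start, object@end, length(object@fixedNodes)))
})

setMethod("show", "PathwaySolution", function(object) {
  cat(sprintf(paste0("PathwaySolution: %d nodes, %d edges in %d ",
                     "component(s); objective %.6g (optimal: %s)\n"),
              length(object@selectedNodes), nrow(object@selectedEdges),
              length(object@components), object@objective,
              object@provenOptimal))
})

#' @describeIn extractComponents nodes of the solution.
#' @param x a \code{PathwaySolution}.
#' @export
setMethod("pathwayNodes", "PathwaySolution", function(x) x@selectedNodes)

#' @describeIn extractComponents edge table of the solution.
#' @export
setMethod("pathwayEdges", "PathwaySolution", function(x) x@selectedEdges)

#' @describeIn extractComponents components, largest first.
#' @export
setMethod("pathwayComponents", "PathwaySolution", function(x) x@components)
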