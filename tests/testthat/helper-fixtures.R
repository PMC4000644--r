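# Builders shared across the test files; everything is generated in code.

makeWeightedGraph <- function(edges, start, end, fixed = character()) {
  ed <- pathSTN:::canonicalEdges(edges[[1L]], edges[[2L]],
                                 if (ncol(edges) >= 3L) edges[[3L]] else NULL)
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = sort(unique(c(ed$a, ed$b, start, end, fixed))))
  new("WeightedPPIGraph", graph = g, start = start, end = end,
      fixedNodes = fixed)
}

## Random small instance generator for solver-vs-oracle comparisons;
## anchors are always n01 and n02, fixed nodes appear with probability
## fixedProb (some draws are deliberately infeasible).
randomWeightedGraph <- function(seed, nNodes = 8, maxEdges = 14,
                                fixedProb = 0.5) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(nNodes))
  ne <- sample(5:maxEdges, 1L)
  a <- ids[sample(nNodes, ne, TRUE)]
  b <- ids[sample(nNodes, ne, TRUE)]
  keep <- a != b
  ed <- data.frame(a = a[keep], b = b[keep],
                   w = round(stats::runif(sum(keep)), 3))
  fixed <- if (stats::runif(1) < fixedProb) {
    sample(ids, sample(1:2, 1L))
  } else {
    character()
  }
  makeWeightedGraph(ed, ids[1L], ids[2L], fixed)
}

toyExpression <- function(m, group = NULL) {
  cd <- S4Vectors::DataFrame(row.names = colnames(m))
  cd$sample_id <- colnames(m)
  if (!is.null(group)) {
    cd$group <- group
    cd$response <- group - mean(group)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m), colData = cd,
    metadata = list(standardized = FALSE))
}

## Objective/edge-set comparison of the exact solver against enumeration;
## both may legitimately raise the structured infeasibility condition.
expectSolverMatchesOracle <- function(wg, lambda) {
  a <- tryCatch(solveILP(buildILP(wg, lambda)), condition = function(c) c)
  b <- tryCatch(bruteForceOracle(buildILP(wg, lambda)),
                condition = function(c) c)
  if (inherits(a, "condition") || inherits(b, "condition")) {
    expect_s3_class(a, "pathSTN_infeasible")
    expect_s3_class(b, "pathSTN_infeasible")
  } else {
    expect_equal(a@objective, b@objective, tolerance = 1e-9)
    expect_identical(a@selectedEdges, b@selectedEdges)
  }
  invisible(NULL)
}
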