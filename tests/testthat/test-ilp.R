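test_that("edge weights are absolute Pearson correlations", {
  m <- rbind(A = c(1, 2, 3, 4), B = c(1, 3, 2, 4), C = c(4, 3, 2, 1),
             D = c(2, 2, 2, 2))
  colnames(m) <- sprintf("s%d", 1:4)
  se <- toyExpression(m)
  net <- GeneNetwork(data.frame(a = c("A", "A", "A", "A"),
                                b = c("B", "C", "D", "Z")))
  expect_warning(wg <- computeEdgeWeights(net, se, "A", "B"),
                 "zero-variance")
  ed <- networkEdges(wg)
  w <- stats::setNames(ed$weight, paste(ed$a, ed$b))
  expect_equal(w[["A B"]], 0.8)                 # hand-computed Pearson r
  expect_equal(w[["A C"]], 1)                   # |r| of perfect anticorrelation
  expect_equal(w[["A D"]], 0)                   # zero variance
  expect_equal(w[["A Z"]], 0)                   # unmeasured endpoint
})

test_that("identifier matching is case-insensitive and drops absentees", {
  m <- rbind(Abc = c(1, 2, 3, 4), XyZ = c(1, 2, 3, 5))
  colnames(m) <- sprintf("s%d", 1:4)
  se <- toyExpression(m)
  net <- GeneNetwork(data.frame(a = "ABC", b = "XYZ"))
  expect_warning(
    wg <- computeEdgeWeights(net, se, "abc", "xyz",
                             fixedNodes = c("ABC", "missing")),
    "missing")
  expect_identical(wg@start, "ABC")
  expect_identical(wg@fixedNodes, "ABC")
  expect_gt(networkEdges(wg)$weight, 0.98)
})

test_that("signed weighting preserves the correlation sign", {
  m <- rbind(A = c(1, 2, 3, 4), C = c(4, 3, 2, 1))
  colnames(m) <- sprintf("s%d", 1:4)
  wg <- computeEdgeWeights(GeneNetwork(data.frame(a = "A", b = "C")),
                           toyExpression(m), "A", "C", signed = TRUE)
  expect_equal(networkEdges(wg)$weight, -1)
})

test_that("instances are built on canonical edges with validated anchors", {
  wg <- makeWeightedGraph(data.frame(a = c("S", "A", "E"),
                                     b = c("A", "E", "S"),
                                     w = c(0.5, 0.6, 0.7)), "S", "E")
  inst <- buildILP(wg, 0.65)
  expect_equal(nrow(inst@edges), 3L)
  expect_equal(length(inst@nodes), 3L)
  expect_error(buildILP(wg, 0), "positive")

  iso <- makeWeightedGraph(data.frame(a = "S", b = "A", w = 1), "S", "E")
  err <- tryCatch(buildILP(iso, 0.5), condition = identity)
  expect_s3_class(err, "pathSTN_infeasible")
  expect_match(conditionMessage(err), "E")

  ## a fixed node with graph degree 1 cannot satisfy its constraint
  wgFix <- makeWeightedGraph(data.frame(a = c("S", "F"), b = c("E", "S"),
                                        w = c(0.9, 0.9)),
                             "S", "E", fixed = "F")
  errF <- tryCatch(buildILP(wgFix, 0.5), condition = identity)
  expect_s3_class(errF, "pathSTN_infeasible")
  expect_true("F" %in% errF$nodes)
})

test_that("worked toy instances solve to their enumerated optima", {
  single <- makeWeightedGraph(data.frame(a = "S", b = "E", w = 0.9),
                              "S", "E")
  sol <- solveILP(buildILP(single, 0.65))
  expect_equal(sol@objective, -0.25)
  expect_true(sol@provenOptimal)
  expect_equal(nrow(sol@selectedEdges), 1L)

  routes <- makeWeightedGraph(
    data.frame(a = c("S", "A", "S", "B"), b = c("A", "E", "B", "E"),
               w = c(0.9, 0.9, 0.2, 0.2)), "S", "E")
  s2 <- solveILP(buildILP(routes, 0.3))
  expect_equal(s2@objective, -1.2)
  expect_setequal(paste(s2@selectedEdges$a, s2@selectedEdges$b),
                  c("A S", "A E"))
  s3 <- solveILP(buildILP(routes, 0.95))
  expect_equal(s3@objective, 0.1, tolerance = 1e-9)
  expect_setequal(unique(c(s3@selectedEdges$a, s3@selectedEdges$b)),
                  c("S", "A", "E"))
})

test_that("fixed nodes are forced into the optimum at degree two", {
  wg <- makeWeightedGraph(
    data.frame(a = c("S", "A", "S", "F", "F"),
               b = c("A", "E", "E", "A", "E"),
               w = c(0.9, 0.9, 0.8, 0.05, 0.05)),
    "S", "E", fixed = "F")
  sol <- solveILP(buildILP(wg, 0.4))
  expect_true("F" %in% sol@selectedNodes)
  degF <- sum(sol@selectedEdges$a == "F" | sol@selectedEdges$b == "F")
  expect_gte(degF, 2L)
  expect_identical(sol@selectedEdges,
                   bruteForceOracle(buildILP(wg, 0.4))@selectedEdges)
})

test_that("solver and enumeration oracle agree on random instances", {
  for (seed in 1:30) {
    wg <- randomWeightedGraph(seed)
    expectSolverMatchesOracle(wg, round(runif(1, 0.1, 0.9), 2))
  }
})

test_that("every solution satisfies the constraints re-checked
          independently", {
  for (seed in 31:40) {
    wg <- randomWeightedGraph(seed, fixedProb = 0.3)
    inst <- tryCatch(buildILP(wg, 0.5), condition = identity)
    if (inherits(inst, "condition")) next
    sol <- tryCatch(solveILP(inst), condition = identity)
    if (inherits(sol, "condition")) next
    sel <- paste(inst@edges$a, inst@edges$b) %in%
      paste(sol@selectedEdges$a, sol@selectedEdges$b)
    expect_true(pathSTN:::checkAssignment(inst, sel))
    expect_equal(sol@objective,
                 -sum(sol@selectedEdges$weight) +
                   0.5 * nrow(sol@selectedEdges),
                 tolerance = 1e-9)
    expect_true(all(c(sol@selectedEdges$a, sol@selectedEdges$b) %in%
                      sol@selectedNodes))
  }
})

test_that("lambda sweeps shrink the network monotonically", {
  set.seed(77)
  ids <- sprintf("v%d", 1:6)
  ed <- data.frame(a = c("v1", "v2", "v3", "v4", "v5", "v1", "v2"),
                   b = c("v2", "v3", "v4", "v5", "v6", "v6", "v5"),
                   w = c(0.9, 0.8, 0.7, 0.85, 0.9, 0.6, 0.3))
  wg <- makeWeightedGraph(ed, "v1", "v6")
  sw <- sweepLambda(wg, c(0.05, 0.3, 0.5, 0.8, 0.95))
  expect_true(all(diff(sw$n_edges) <= 0))
  ## tiny penalty: every positive-weight edge is selectable and selected
  expect_equal(sw$n_edges[1], nrow(ed))
  ## penalty above every weight: only the cheapest feasible route remains
  oracleBig <- bruteForceOracle(buildILP(wg, 0.95))
  expect_equal(sw$objective[5], oracleBig@objective, tolerance = 1e-9)
  expect_equal(sw$n_edges[5], nrow(oracleBig@selectedEdges))
})

test_that("component reports label roles and anchor connectivity", {
  single <- makeWeightedGraph(data.frame(a = "S", b = "E", w = 0.9),
                              "S", "E")
  rep1 <- extractComponents(solveILP(buildILP(single, 0.65)))
  expect_length(rep1$components, 1L)
  expect_true(rep1$anchorsConnected)
  expect_setequal(rep1$report$role, c("start", "end"))

  ## two disjoint pieces: an anchor edge plus a forced remote triangle
  wg2 <- makeWeightedGraph(
    data.frame(a = c("S", "F", "G", "H"), b = c("E", "G", "H", "F"),
               w = c(0.9, 0.1, 0.1, 0.1)),
    "S", "E", fixed = "F")
  rep2 <- extractComponents(solveILP(buildILP(wg2, 0.4)))
  expect_length(rep2$components, 2L)
  expect_true(rep2$anchorsConnected)      # S and E share the anchor edge
  roles <- stats::setNames(rep2$report$role, rep2$report$node)
  expect_identical(roles[["F"]], "selected_gene")
  expect_identical(roles[["G"]], "ilp_added")
  expect_true(all(lengths(rep2$components) >= 2L))

  ## anchors satisfied in separate components: connectivity flag drops
  wg3 <- makeWeightedGraph(
    data.frame(a = c("S", "A", "B", "E", "C", "D"),
               b = c("A", "B", "S", "C", "D", "E"),
               w = rep(0.9, 6)),
    "S", "E")
  rep3 <- extractComponents(solveILP(buildILP(wg3, 0.4)))
  expect_length(rep3$components, 2L)
  expect_false(rep3$anchorsConnected)
})

test_that("path recovery holds under strong planted correlation", {
  hits <- vapply(1:10, function(s) {
    cfg <- simulationConfig(nGenes = 40, nSupport = 0, effectSize = 0,
                            pathLength = 3, pathCorrelation = 0.95,
                            seed = s)
    sim <- simulatePPIGraph(cfg)
    dat <- simulateExpression(cfg, sim$truth)
    wg <- computeEdgeWeights(sim$network, dat$expression,
                             sim$truth@start, sim$truth@end)
    sol <- solveILP(buildILP(wg, 0.6))
    got <- paste(sol@selectedEdges$a, sol@selectedEdges$b)
    all(paste(sim$truth@plantedEdges$a,
              sim$truth@plantedEdges$b) %in% got)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
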