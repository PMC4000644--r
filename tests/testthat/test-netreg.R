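## Shared toy problem: full-rank standardized design.
standardizedDesign <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  colnames(X) <- sprintf("g%02d", seq_len(p))
  X
}

test_that("the penalized criterion evaluates exactly", {
  X <- standardizedDesign(5, 3, 1)
  mu <- c(1, -1, 0.5, 0, -0.5)
  expect_equal(netregObjective(rep(0, 3), X, mu, 2, 3,
                               diag(3)), sum(mu^2))
  bh <- drop(solve(crossprod(X), crossprod(X, mu)))
  rss <- sum((mu - X %*% bh)^2)
  expect_equal(netregObjective(bh, X, mu, 0, 0), rss)
  b <- c(0.3, -0.2, 0.1)
  expect_equal(netregObjective(b, X, mu, 1, 2, diag(3)),
               sum((mu - X %*% b)^2) + sum(abs(b)) + 2 * sum(b^2))
  expect_error(netregObjective(b, X, mu[1:3], 0, 0), "nrow")
})

test_that("with no penalty the solver matches the normal equations", {
  X <- standardizedDesign(8, 3, 2)
  mu <- drop(X %*% c(2, -1, 0)) + rnorm(8, sd = 0.1)
  mu <- mu - mean(mu)
  fit <- solveNetreg(X, mu, 0, 0)
  expect_equal(unname(fit$beta),
               unname(drop(solve(crossprod(X), crossprod(X, mu)))),
               tolerance = 1e-6)
})

test_that("a single standardized predictor soft-thresholds at lambda1/2", {
  set.seed(3)
  x <- rnorm(12)
  x <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "g"))
  mu <- 0.8 * x + rnorm(12, sd = 0.2)
  mu <- mu - mean(mu)
  for (lam1 in c(0.1, 0.5, 2 * abs(sum(x * mu)) + 1)) {
    fit <- solveNetreg(X, mu, lam1, 0)
    closed <- sign(sum(x * mu)) * max(abs(sum(x * mu)) - lam1 / 2, 0)
    expect_equal(unname(fit$beta), closed, tolerance = 1e-7)
    ## the closed form itself, checked against a dense grid search
    grid <- seq(-2, 2, by = 1e-4)
    vals <- vapply(grid,
                   function(b) sum((mu - x * b)^2) + lam1 * abs(b),
                   numeric(1))
    expect_equal(closed, grid[which.min(vals)], tolerance = 1e-3)
  }
})

test_that("a dominating lambda1 zeroes every coefficient", {
  X <- standardizedDesign(10, 4, 4)
  mu <- rnorm(10)
  mu <- mu - mean(mu)
  lamBig <- 10 * max(abs(2 * crossprod(X, mu)))
  fit <- solveNetreg(X, mu, lamBig, 0)
  expect_equal(unname(fit$beta), rep(0, 4))
})

test_that("the objective trace never increases and the fit is a minimum", {
  X <- standardizedDesign(20, 8, 5)
  set.seed(5)
  mu <- drop(X %*% c(3, -2, rep(0, 6))) + rnorm(20, sd = 0.3)
  mu <- mu - mean(mu)
  net <- GeneNetwork(data.frame(a = colnames(X)[1:7], b = colnames(X)[2:8]))
  L <- buildLaplacian(net, colnames(X))
  fit <- solveNetreg(X, mu, 0.4, 0.7, L)
  expect_true(all(diff(fit$trace) <= 1e-8 * (1 + abs(fit$trace[-1]))))
  base <- netregObjective(fit$beta, X, mu, 0.4, 0.7, L)
  expect_equal(base, fit$objective, tolerance = 1e-9)
  set.seed(6)
  worse <- vapply(seq_len(1000), function(i) {
    netregObjective(fit$beta + 1e-3 * rnorm(8), X, mu, 0.4, 0.7, L)
  }, numeric(1))
  expect_true(all(worse >= base - 1e-12))
})

test_that("the Laplacian route agrees with an independent lasso solver", {
  library(glmnet)
  X <- standardizedDesign(25, 10, 7)
  set.seed(7)
  mu <- drop(X %*% c(2, 2, rep(0, 8))) + rnorm(25, sd = 0.5)
  mu <- mu - mean(mu)
  net <- GeneNetwork(data.frame(a = colnames(X)[c(1, 3)],
                                b = colnames(X)[c(2, 4)]))
  L <- buildLaplacian(net, colnames(X))
  lam1 <- 0.6
  lam2 <- 1.3
  fit <- solveNetreg(X, mu, lam1, lam2, L)
  ## independent route: augment the design by hand, then glmnet
  eg <- eigen(L, symmetric = TRUE)
  S <- sqrt(pmax(eg$values, 0)) * t(eg$vectors)
  Xa <- rbind(X, sqrt(lam2) * S)
  ya <- c(mu, rep(0, nrow(S)))
  gfit <- glmnet(Xa, ya, lambda = lam1 / (2 * nrow(Xa)),
                 standardize = FALSE, intercept = FALSE,
                 thresh = 1e-14)
  expect_equal(unname(fit$beta), as.numeric(gfit$beta), tolerance = 1e-5)
})

test_that("PSD is required of the Laplacian argument", {
  X <- standardizedDesign(6, 2, 8)
  mu <- rnorm(6)
  bad <- matrix(c(1, 2, 2, 1), 2)      # eigenvalues 3 and -1
  expect_error(solveNetreg(X, mu, 0.1, 0.5, bad), "positive semi-definite")
})

test_that("cross-validation honors folds, single points and sparsity ties", {
  X <- standardizedDesign(20, 5, 9)
  set.seed(9)
  mu <- drop(X %*% c(2, rep(0, 4))) + rnorm(20, sd = 0.3)
  mu <- mu - mean(mu)
  g1 <- penaltyGrid(0.7, 0, nFolds = 5, cvSeed = 1)
  cv <- crossValidate(X, mu, g1)
  expect_equal(nrow(cv$cvTable), 1L)
  expect_equal(cv$lambda1, 0.7)
  expect_error(crossValidate(X[1:4, ], mu[1:4],
                             penaltyGrid(0.5, 0, nFolds = 10)), "nFolds")
})

test_that("a null model wins cross-validation on pure noise", {
  wins <- vapply(1:50, function(seed) {
    set.seed(seed)
    X <- standardizedDesign(20, 5, seed + 100)
    mu <- rnorm(20)
    mu <- mu - mean(mu)
    lamBig <- 10 * max(abs(2 * crossprod(X, mu)))
    cv <- crossValidate(X, mu, penaltyGrid(c(0.01, lamBig), 0,
                                           nFolds = 10, cvSeed = seed))
    cv$lambda1 == lamBig
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("CV-tuned fits recover a strong planted support", {
  recovered <- vapply(1:9, function(seed) {
    cfg <- simulationConfig(nGenes = 60, nSupport = 5, effectSize = 2,
                            pathLength = 3, seed = seed)
    sim <- simulatePPIGraph(cfg)
    dat <- simulateExpression(cfg, sim$truth)
    fs <- standardizeExpression(anovaFilter(dat$expression))
    res <- fitNetreg(fs, sim$network, cvSeed = seed)
    length(intersect(selectedGenes(res), sim$truth@supportGenes))
  }, numeric(1))
  expect_gte(median(recovered), 4)
})

test_that("selected genes follow the magnitude ordering and tolerance", {
  res <- new("SelectionResult",
             beta = c(g1 = 0.5, g2 = 0, g3 = -0.2, g4 = 1e-8),
             lambda1 = 1, lambda2 = 0, cvError = 0.1,
             cvTable = data.frame(), objective = 1, sweeps = 1)
  expect_identical(selectedGenes(res), c("g1", "g3"))
  resZero <- new("SelectionResult", beta = c(a = 0, b = 0), lambda1 = 1,
                 lambda2 = 0, cvError = 0.1, cvTable = data.frame(),
                 objective = 1, sweeps = 1)
  expect_identical(selectedGenes(resZero), character())
})

test_that("the selected-gene count shrinks along the lambda1 path", {
  cfg <- simulationConfig(nGenes = 40, seed = 13)
  sim <- simulatePPIGraph(cfg)
  dat <- simulateExpression(cfg, sim$truth)
  fs <- standardizeExpression(anovaFilter(dat$expression))
  X <- t(SummarizedExperiment::assay(fs))
  mu <- SummarizedExperiment::colData(fs)$response
  lamMax <- 2 * max(abs(crossprod(X, mu)))
  path <- lamMax * c(1, 0.5, 0.25, 0.1, 0.03, 0.01)
  counts <- vapply(path, function(l1) {
    sum(abs(solveNetreg(X, mu, l1, 0)$beta) > 1e-8)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))      # path is largest-to-smallest
})

test_that("standardization gives unit sum-of-squares rows and a centered
          response", {
  set.seed(30)
  m <- matrix(rnorm(40, sd = 3) + 5, 5, 8,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:8)))
  se <- toyExpression(m, group = rep(0:3, each = 2))
  std <- standardizeExpression(se)
  ms <- SummarizedExperiment::assay(std)
  expect_equal(unname(rowMeans(ms)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(rowSums(ms^2)), rep(1, 5), tolerance = 1e-12)
  expect_equal(sum(SummarizedExperiment::colData(std)$response), 0)
  m[2, ] <- 7
  expect_error(standardizeExpression(toyExpression(m, rep(0:3, each = 2))),
               "g2")
})

test_that("the ANOVA prefilter keeps strong genes and drops degenerate
          ones", {
  set.seed(31)
  grp <- rep(0:3, each = 5)
  strong <- grp + rnorm(20, sd = 0.01)
  flat <- rnorm(20)
  const <- rep(2, 20)
  m <- rbind(strong = strong, flat = flat, const = const)
  colnames(m) <- sprintf("s%02d", 1:20)
  se <- toyExpression(m, group = grp)
  expect_warning(kept <- anovaFilter(se, alpha = 0.05), "degenerate")
  expect_true("strong" %in% rownames(kept))
  expect_false("const" %in% rownames(kept))
  ## independent textbook F statistic for the strong gene
  gm <- tapply(strong, grp, mean)
  ssb <- 5 * sum((gm - mean(strong))^2)
  ssw <- sum((strong - gm[as.character(grp)])^2)
  f <- (ssb / 3) / (ssw / 16)
  expect_lt(stats::pf(f, 3, 16, lower.tail = FALSE), 1e-10)

  expect_warning(all2 <- anovaFilter(se, alpha = 1), "degenerate")
  expect_setequal(rownames(all2), c("strong", "flat"))

  expect_warning(lit <- anovaFilter(se, alpha = 0.05, mode = "literal"),
                 "degenerate")
  expect_false("strong" %in% rownames(lit))
  expect_true("flat" %in% rownames(lit))
})
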