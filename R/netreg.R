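#' Network-constrained regularization criterion
#'
#' Value of the penalized least-squares criterion
#' \deqn{L(\lambda_1, \lambda_2, \beta) = (\mu - X\beta)^T(\mu - X\beta)
#'   + \lambda_1 \|\beta\|_1 + \lambda_2 \beta^T L \beta,}
#' the unscaled residual sum of squares plus an L1 penalty and a graph
#' smoothness penalty through the normalized Laplacian.
#'
#' @param beta coefficient vector (length p).
#' @param X n-by-p design matrix (samples by genes).
#' @param mu centered response (length n).
#' @param lambda1 nonnegative L1 penalty.
#' @param lambda2 nonnegative Laplacian penalty.
#' @param L p-by-p Laplacian (may be \code{NULL} when \code{lambda2 == 0}).
#' @return the scalar criterion value.
#' @export
netregObjective <- function(beta, X, mu, lambda1, lambda2, L = NULL) {
  stopifnot(ncol(X) == length(beta), nrow(X) == length(mu))
  r <- mu - drop(X %*% beta)
  val <- sum(r^2) + lambda1 * sum(abs(beta))
  if (lambda2 > 0) {
    stopifnot(!is.null(L), nrow(L) == length(beta), ncol(L) == length(beta))
    val <- val + lambda2 * drop(crossprod(beta, L %*% beta))
  }
  val
}

## Factor L = S'S by symmetric eigendecomposition (S = Lambda^{1/2} U'),
## clamping tiny negative eigenvalues; rows with zero eigenvalue are dropped
## (they contribute nothing to beta' L beta).
laplacianFactor <- function(L, clamp = 1e-10) {
  eg <- eigen(L, symmetric = TRUE)
  vals <- eg$values
  if (any(vals < -clamp)) {
    stop("Laplacian is not positive semi-definite (eigenvalue ",
         format(min(vals)), ")")
  }
  vals[vals < 0] <- 0
  keep <- vals > 0
  sqrt(vals[keep]) * t(eg$vectors[, keep, drop = FALSE])
}

#' Solve the network-constrained lasso
#'
#' Minimizes [netregObjective()] by the lasso-type reduction: the Laplacian
#' is factored as \eqn{L = S^T S}, the design is augmented with
#' \eqn{\sqrt{\lambda_2} S} rows and the response with zeros, and the
#' resulting pure L1 problem is solved by cyclic coordinate descent with
#' residual updating. Convergence is declared when the largest coefficient
#' change in a sweep falls below \code{tol}; the criterion value is checked
#' to be non-increasing after every sweep.
#'
#' @inheritParams netregObjective
#' @param betaInit optional warm start (default zero).
#' @param tol convergence threshold on \eqn{\max_j |\Delta\beta_j|}
#'   (default 1e-7).
#' @param maxSweeps sweep budget; exceeding it is an error carrying the
#'   objective trace.
#' @return a list with \code{beta} (named by the columns of \code{X}),
#'   \code{objective}, \code{sweeps} and the per-sweep objective
#'   \code{trace}.
#' @examples
#' set.seed(1)
#' X <- scale(matrix(rnorm(40), 8, 5))
#' mu <- drop(X %*% c(2, 0, 0, -1, 0)) + rnorm(8, sd = 0.1)
#' fit <- solveNetreg(X, mu - mean(mu), lambda1 = 0.5, lambda2 = 0)
#' fit$beta
#' @export
solveNetreg <- function(X, mu, lambda1, lambda2, L = NULL, betaInit = NULL,
                        tol = 1e-7, maxSweeps = 1e4) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, nrow(X) == length(mu))
  p <- ncol(X)
  if (lambda2 > 0) {
    if (is.null(L)) stop("lambda2 > 0 requires a Laplacian")
    S <- laplacianFactor(L)
    Xa <- rbind(X, sqrt(lambda2) * S)
    ya <- c(mu, rep(0, nrow(S)))
  } else {
    Xa <- X
    ya <- mu
  }
  beta <- if (is.null(betaInit)) rep(0, p) else as.numeric(betaInit)
  stopifnot(length(beta) == p)
  ## Gram-matrix (covariance) updates: each coordinate step costs O(p)
  ## instead of O(n + p) on the augmented design.
  G <- crossprod(Xa)
  q <- drop(crossprod(Xa, ya))
  c0 <- sum(ya^2)
  diagG <- diag(G)
  Gb <- drop(G %*% beta)
  obj <- function() {
    c0 - 2 * sum(q * beta) + sum(beta * Gb) + lambda1 * sum(abs(beta))
  }
  trace <- obj()
  sweeps <- 0L
  thr <- lambda1 / 2
  repeat {
    maxDelta <- 0
    for (j in seq_len(p)) {
      if (diagG[j] == 0) next
      bj <- beta[j]
      rho <- q[j] - Gb[j] + diagG[j] * bj
      shrunk <- abs(rho) - thr              # scalar soft-threshold
      bnew <- if (shrunk <= 0) 0 else sign(rho) * shrunk / diagG[j]
      if (bnew != bj) {
        Gb <- Gb + G[, j] * (bnew - bj)
        beta[j] <- bnew
        maxDelta <- max(maxDelta, abs(bnew - bj))
      }
    }
    sweeps <- sweeps + 1L
    cur <- obj()
    last <- trace[length(trace)]
    if (cur > last + 1e-8 * (1 + abs(last))) {
      stop("internal error: objective increased across a sweep")
    }
    trace <- c(trace, cur)
    if (maxDelta < tol) break
    if (sweeps >= maxSweeps) {
      cond <- structure(
        class = c("pathSTN_noConvergence", "error", "condition"),
        list(message = sprintf(
               "coordinate descent did not converge in %d sweeps", sweeps),
             call = NULL, trace = trace))
      stop(cond)
    }
  }
  names(beta) <- colnames(X)
  objective <- sum((ya - drop(Xa %*% beta))^2) +
    lambda1 * sum(abs(beta))                 # exact, not Gram-accumulated
  list(beta = beta, objective = objective, sweeps = sweeps,
       trace = unname(trace))
}

#' Cross-validate the penalty pair
#'
#' Folds are formed by a seeded shuffle with sizes differing by at most
#' one. For every grid point the mean held-out squared prediction error is
#' recorded and the point with the smallest error wins. Ties break toward
#' larger \code{lambda1}, then larger \code{lambda2} (the sparser,
#' smoother model); two points are tied when their CV errors differ by
#' less than the standard error of the minimizing point's fold means — CV
#' errors that close are statistically indistinguishable at these sample
#' sizes, so the parsimonious model is preferred (the usual
#' one-standard-error convention). Coordinate descent is warm-started
#' along the \code{lambda1} path within each \code{lambda2}.
#'
#' @inheritParams netregObjective
#' @param grid a [PenaltyGrid-class] (see [penaltyGrid()]).
#' @return a list with the chosen \code{lambda1}, \code{lambda2} and the
#'   full \code{cvTable} (lambda1, lambda2, cv_error).
#' @export
crossValidate <- function(X, mu, grid, L = NULL) {
  stopifnot(is(grid, "PenaltyGrid"))
  validObject(grid)
  n <- nrow(X)
  k <- grid@nFolds
  if (n < k) stop("need at least nFolds samples")
  if (any(grid@lambda2 > 0) && is.null(L)) {
    stop("nonzero lambda2 values require a Laplacian")
  }
  foldId <- integer(n)
  foldId[withSeed(grid@cvSeed, sample(n))] <- rep_len(seq_len(k), n)
  lam1Desc <- rev(grid@lambda1)              # large-to-small for warm starts
  cvTable <- NULL
  for (lam2 in grid@lambda2) {
    errs <- matrix(NA_real_, length(lam1Desc), k)
    for (f in seq_len(k)) {
      tr <- foldId != f
      if (sum(!tr) < 1L) stop("empty fold")
      warm <- NULL
      for (i in seq_along(lam1Desc)) {
        fit <- solveNetreg(X[tr, , drop = FALSE], mu[tr], lam1Desc[i],
                           lam2, L, betaInit = warm)
        warm <- fit$beta
        pred <- drop(X[!tr, , drop = FALSE] %*% fit$beta)
        errs[i, f] <- mean((mu[!tr] - pred)^2)
      }
    }
    cvTable <- rbind(cvTable,
                     data.frame(lambda1 = lam1Desc, lambda2 = lam2,
                                cv_error = rowMeans(errs),
                                cv_se = apply(errs, 1L, stats::sd) /
                                  sqrt(k)))
  }
  iMin <- which.min(cvTable$cv_error)
  tied <- cvTable$cv_error <= cvTable$cv_error[iMin] + cvTable$cv_se[iMin]
  cand <- cvTable[tied, ]
  best <- cand[order(-cand$lambda1, -cand$lambda2), ][1L, ]
  cvTable <- cvTable[order(cvTable$lambda2, cvTable$lambda1), ]
  rownames(cvTable) <- NULL
  list(lambda1 = best$lambda1, lambda2 = best$lambda2,
       cvError = best$cv_error, cvTable = cvTable)
}

#' Construct a penalty grid
#'
#' @param lambda1 positive L1 penalty values (sorted ascending).
#' @param lambda2 nonnegative Laplacian penalty values (sorted ascending).
#' @param nFolds CV folds (default 10).
#' @param cvSeed fold-shuffle seed.
#' @return a [PenaltyGrid-class].
#' @export
penaltyGrid <- function(lambda1, lambda2 = 0, nFolds = 10, cvSeed = 1) {
  new("PenaltyGrid", lambda1 = sort(as.numeric(lambda1)),
      lambda2 = sort(as.numeric(lambda2)), nFolds = as.integer(nFolds),
      cvSeed = as.integer(cvSeed))
}

#' Data-driven default penalty grid
#'
#' \code{lambda1} runs geometrically from the smallest value that zeroes
#' every coefficient, \eqn{\lambda_{max} = 2 \max_j |x_j^T \mu|}, down to
#' \code{lambda1MinRatio} times that value over \code{nLambda1} log-spaced
#' points (the usual regularization-path construction); \code{lambda2}
#' defaults to \{0, 0.5, 2\}, spanning no smoothing to strong smoothing on
#' the scale of unit-sum-of-squares predictors.
#'
#' @inheritParams netregObjective
#' @param nLambda1 number of lambda1 points (default 25).
#' @param lambda1MinRatio smallest lambda1 as a fraction of
#'   \eqn{\lambda_{max}} (default 1e-3).
#' @param lambda2 Laplacian penalty values.
#' @param nFolds,cvSeed passed to [penaltyGrid()].
#' @return a [PenaltyGrid-class].
#' @export
defaultPenaltyGrid <- function(X, mu, nLambda1 = 25, lambda1MinRatio = 1e-3,
                               lambda2 = c(0, 0.5, 2), nFolds = 10,
                               cvSeed = 1) {
  lamMax <- 2 * max(abs(crossprod(X, mu)))
  if (lamMax <= 0) lamMax <- 1
  penaltyGrid(lamMax * exp(seq(log(lambda1MinRatio), 0,
                               length.out = nLambda1)),
              lambda2, nFolds, cvSeed)
}

#' Fit the network-constrained regression on an expression object
#'
#' Orchestrates the selection stage: builds the normalized Laplacian on the
#' (post-filter) gene set, cross-validates the penalty pair and refits on
#' all samples at the chosen penalties.
#'
#' @param se a standardized \code{SummarizedExperiment} (see
#'   [standardizeExpression()]) with \code{response} in \code{colData}.
#' @param net the gene network supplying the Laplacian penalty.
#' @param grid a [PenaltyGrid-class]; defaults to [defaultPenaltyGrid()].
#' @param cvSeed fold seed used when \code{grid} is NULL.
#' @return a [SelectionResult-class].
#' @export
fitNetreg <- function(se, net, grid = NULL, cvSeed = 1) {
  if (!isTRUE(S4Vectors::metadata(se)$standardized)) {
    stop("expression must be standardized first; see standardizeExpression()")
  }
  X <- t(SummarizedExperiment::assay(se, "exprs"))
  mu <- SummarizedExperiment::colData(se)$response
  if (is.null(mu)) stop("colData needs a `response` column")
  L <- buildLaplacian(net, colnames(X))
  if (is.null(grid)) grid <- defaultPenaltyGrid(X, mu, cvSeed = cvSeed)
  cv <- crossValidate(X, mu, grid, L)
  fit <- solveNetreg(X, mu, cv$lambda1, cv$lambda2, L)
  new("SelectionResult", beta = fit$beta, lambda1 = cv$lambda1,
      lambda2 = cv$lambda2, cvError = cv$cvError, cvTable = cv$cvTable,
      objective = fit$objective, sweeps = as.numeric(fit$sweeps))
}

#' @describeIn fitNetreg genes with \eqn{|\beta|} strictly above
#'   \code{tolerance} (default 1e-8), ordered by descending magnitude —
#'   the "significant genes" passed on as fixed pathway members.
#' @param x a [SelectionResult-class].
#' @param tolerance zero threshold on \eqn{|\beta|}.
#' @export
setMethod("selectedGenes", "SelectionResult", function(x, tolerance = 1e-8) {
  b <- x@beta[abs(x@beta) > tolerance]
  names(b)[order(-abs(b))]
})

#' @export
setMethod("coef", "SelectionResult", function(object, ...) object@beta)

setMethod("show", "SelectionResult", function(object) {
  sel <- selectedGenes(object)
  cat(sprintf(paste0("SelectionResult: %d/%d nonzero coefficients ",
                     "(lambda1=%.4g, lambda2=%.4g, CV error %.4g)\n"),
              length(sel), length(object@beta), object@lambda1,
              object@lambda2, object@cvError))
  if (length(sel)) {
    cat("  top genes:", paste(utils::head(sel, 8), collapse = ", "), "\n")
  }
})
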