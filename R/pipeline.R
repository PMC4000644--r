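#' Validate a run configuration
#'
#' Accepts a YAML or JSON file path, or an equivalent list. Every violation
#' is collected (not first-error-only); if any are found the function stops
#' with a condition of class \code{pathSTN_configError} whose
#' \code{errors} field lists all of them.
#'
#' Recognized fields (with defaults): \code{mode} ("synthetic" or
#' "user-data"), \code{seed}, \code{alpha} (0.05), \code{anova_mode}
#' ("retain"), \code{lambda2_grid} (0, 0.5, 2), \code{n_folds} (10),
#' \code{ilp_lambda} (0.65), \code{sweep} (optional from/to/by), \code{start}
#' and \code{end} anchors plus \code{expression}/\code{phenotypes}/
#' \code{network}/\code{ppi} paths in user-data mode, \code{signed_weights}
#' (FALSE), \code{out_dir}, and a \code{simulation} block of
#' [simulationConfig()] arguments in synthetic mode.
#'
#' @param x a file path or a named list.
#' @return the validated configuration as a list of class \code{RunConfig}.
#' @export
validateConfig <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      stop(structure(class = c("pathSTN_configError", "error", "condition"),
                     list(message = paste0("config file not found: ", x),
                          call = NULL,
                          errors = paste0("config file not found: ", x))))
    }
    x <- if (grepl("\\.json$", x, ignore.case = TRUE)) {
      jsonlite::read_json(x, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(x)
    }
  }
  stopifnot(is.list(x))
  defaults <- list(mode = "synthetic", seed = NULL, alpha = 0.05,
                   anova_mode = "retain", lambda2_grid = c(0, 0.5, 2),
                   n_folds = 10, ilp_lambda = 0.65, sweep = NULL,
                   start = NULL, end = NULL, expression = NULL,
                   phenotypes = NULL, network = NULL, ppi = NULL,
                   signed_weights = FALSE, out_dir = NULL,
                   simulation = list())
  cfg <- utils::modifyList(defaults, x)
  errors <- character()
  addErr <- function(msg) errors <<- c(errors, msg)
  if (!cfg$mode %in% c("synthetic", "user-data")) {
    addErr("`mode` must be \"synthetic\" or \"user-data\"")
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha > 1) {
    addErr("`alpha` must lie in (0, 1]")
  }
  if (!cfg$anova_mode %in% c("retain", "literal")) {
    addErr("`anova_mode` must be \"retain\" or \"literal\"")
  }
  if (!is.numeric(cfg$ilp_lambda) || cfg$ilp_lambda <= 0) {
    addErr("`ilp_lambda` must be positive")
  }
  if (!is.numeric(cfg$n_folds) || cfg$n_folds < 2) {
    addErr("`n_folds` must be >= 2")
  }
  if (!is.null(cfg$sweep) &&
      !(is.numeric(cfg$sweep) && length(cfg$sweep) == 3L &&
        cfg$sweep[1L] > 0 && cfg$sweep[2L] >= cfg$sweep[1L] &&
        cfg$sweep[3L] > 0)) {
    addErr("`sweep` must be numeric (from, to, by) with 0 < from <= to")
  }
  if (identical(cfg$mode, "synthetic")) {
    if (is.null(cfg$seed)) addErr("synthetic mode requires `seed`")
    simArgs <- cfg$simulation
    badSim <- setdiff(names(simArgs), names(formals(simulationConfig)))
    if (length(badSim)) {
      addErr(paste0("unknown simulation field(s): ",
                    paste(badSim, collapse = ", ")))
    }
  } else {
    for (field in c("expression", "phenotypes", "ppi")) {
      if (is.null(cfg[[field]])) {
        addErr(paste0("user-data mode requires `", field, "`"))
      } else if (!file.exists(cfg[[field]])) {
        addErr(paste0("`", field, "` file not found: ", cfg[[field]]))
      }
    }
    if (is.null(cfg$start)) addErr("user-data mode requires anchor `start`")
    if (is.null(cfg$end)) addErr("user-data mode requires anchor `end`")
  }
  if (length(errors)) {
    stop(structure(class = c("pathSTN_configError", "error", "condition"),
                   list(message = paste0("invalid configuration:\n  - ",
                                         paste(errors, collapse = "\n  - ")),
                        call = NULL, errors = errors)))
  }
  structure(cfg, class = c("RunConfig", "list"))
}

#' Run the full two-stage pipeline
#'
#' simulate (or load) \eqn{\to} ANOVA filter \eqn{\to} standardize
#' \eqn{\to} network-constrained selection \eqn{\to} correlation-weighted
#' ILP extraction, writing every intermediate artifact plus a manifest
#' under \code{outDir}. Identical configuration and seed reproduce
#' identical artifacts and manifests, timing fields aside.
#'
#' @param config a [validateConfig()] result, or anything it accepts.
#' @param outDir output directory (overrides \code{out_dir} in the config).
#' @param seed overrides \code{seed} in the config.
#' @return the run manifest (a list), invisibly. Stage counts, penalties,
#'   the ILP objective, component sizes, file digests and timings.
#' @examples
#' \donttest{
#' man <- runPipeline(list(mode = "synthetic", seed = 7,
#'                         simulation = list(nGenes = 40)),
#'                    outDir = tempfile())
#' man$stages$select$selected_genes
#' }
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL) {
  if (!inherits(config, "RunConfig")) config <- validateConfig(config)
  if (!is.null(seed)) config$seed <- seed
  outDir <- outDir %||% config$out_dir %||%
    stop("an output directory is required (out_dir or outDir)")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  manifest <- list(version = as.character(utils::packageVersion("pathSTN")),
                   mode = config$mode, seed = config$seed, stages = list())
  timer <- function() as.numeric(Sys.time())
  stage <- function(name, expr) {
    t0 <- timer()
    res <- tryCatch(expr, error = function(e) {
      e$message <- paste0("stage `", name, "` failed: ",
                          conditionMessage(e))
      e$manifest <- manifest
      stop(e)
    })
    res$wall_clock_s <- timer() - t0
    manifest$stages[[name]] <<- res
    res
  }
  digests <- function(paths) {
    as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
  }

  ## --- inputs -----------------------------------------------------------
  inStage <- stage("inputs", {
    truth <- NULL
    if (config$mode == "synthetic") {
      simArgs <- config$simulation
      simArgs$seed <- simArgs$seed %||% config$seed
      simCfg <- do.call(simulationConfig, simArgs)
      sim <- simulatePPIGraph(simCfg)
      dat <- simulateExpression(simCfg, sim$truth)
      truth <- sim$truth
      net <- sim$network
      ppi <- sim$network        # one graph serves Laplacian and PPI roles
      se <- dat$expression
      fixDir <- file.path(outDir, "inputs")
      writeFixtureSet(fixDir, se, dat$phenotypes,
                      list(network = net), sim$truth)
      start <- sim$truth@start
      end <- sim$truth@end
      files <- list.files(fixDir, full.names = TRUE)
    } else {
      se <- readExpression(config$expression)
      se <- attachPhenotypes(se, readPhenotypes(config$phenotypes))
      ppi <- readNetwork(config$ppi)
      net <- if (is.null(config$network)) ppi else
        readNetwork(config$network)
      start <- config$start
      end <- config$end
      files <- unlist(config[c("expression", "phenotypes", "ppi",
                               "network")])
      files <- files[!is.na(files)]
    }
    list(expression = se, network = net, ppi = ppi, start = start,
         end = end, truth = truth, n_genes = nrow(se),
         n_samples = ncol(se), file_digests = digests(files))
  })
  se0 <- inStage$expression
  truth <- inStage$truth

  ## --- filter + standardize --------------------------------------------
  filt <- stage("filter", {
    seF <- anovaFilter(se0, alpha = config$alpha, mode = config$anova_mode)
    seF <- standardizeExpression(seF)
    list(expression = seF, n_genes = nrow(seF), alpha = config$alpha)
  })

  ## --- selection --------------------------------------------------------
  sel <- stage("select", {
    X <- t(SummarizedExperiment::assay(filt$expression, "exprs"))
    mu <- SummarizedExperiment::colData(filt$expression)$response
    grid <- defaultPenaltyGrid(X, mu, lambda2 = config$lambda2_grid,
                               nFolds = config$n_folds,
                               cvSeed = stageSeed(config$seed %||% 0, "cv"))
    res <- fitNetreg(filt$expression, inStage$network, grid)
    genes <- selectedGenes(res)
    selTab <- data.frame(gene = genes,
                         beta = unname(res@beta[genes]),
                         rank = seq_along(genes))
    utils::write.table(selTab, file.path(outDir, "selected_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res@cvTable, file.path(outDir, "cv_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(lambda1 = res@lambda1, lambda2 = res@lambda2,
                              cv_error = res@cvError,
                              objective = res@objective,
                              selected = genes),
                         file.path(outDir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
    list(result = res, selected_genes = genes,
         n_genes = length(genes), lambda1 = res@lambda1,
         lambda2 = res@lambda2,
         file_digests = digests(file.path(outDir,
           c("selected_genes.tsv", "cv_table.tsv", "fit.json"))))
  })

  ## --- pathway extraction ----------------------------------------------
  path <- stage("pathway", {
    wg <- computeEdgeWeights(inStage$ppi, se0, inStage$start, inStage$end,
                             fixedNodes = sel$selected_genes,
                             signed = isTRUE(config$signed_weights))
    sol <- solveILP(buildILP(wg, config$ilp_lambda))
    comp <- extractComponents(sol)
    writeSolutionNetwork(sol, file.path(outDir, "solution.graphml"),
                         "graphml")
    writeSolutionNetwork(sol, file.path(outDir, "solution.sif"), "sif")
    utils::write.table(comp$report, file.path(outDir, "components.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c("solution.graphml", "solution.sif", "components.tsv")
    if (!is.null(config$sweep)) {
      sw <- sweepLambda(wg, seq(config$sweep[1L], config$sweep[2L],
                                by = config$sweep[3L]))
      utils::write.table(sw, file.path(outDir, "sweep.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, "sweep.tsv")
    }
    jsonlite::write_json(
      list(objective = sol@objective, proven_optimal = sol@provenOptimal,
           constraints_satisfied = TRUE, lambda = config$ilp_lambda,
           n_nodes = length(sol@selectedNodes),
           n_edges = nrow(sol@selectedEdges),
           component_sizes = lengths(comp$components),
           anchors_connected = comp$anchorsConnected),
      file.path(outDir, "solve_report.json"), auto_unbox = TRUE,
      digits = NA)
    list(solution = sol, objective = sol@objective,
         n_nodes = length(sol@selectedNodes),
         n_edges = nrow(sol@selectedEdges),
         component_sizes = lengths(comp$components),
         anchors_connected = comp$anchorsConnected,
         file_digests = digests(file.path(outDir,
                                          c(files, "solve_report.json"))))
  })

  ## gene counts shrink monotonically through filtering and selection
  stopifnot(inStage$n_genes >= filt$n_genes,
            filt$n_genes >= sel$n_genes)
  manifest$counts <- list(genes_input = inStage$n_genes,
                          genes_after_filter = filt$n_genes,
                          genes_selected = sel$n_genes,
                          network_nodes = path$n_nodes,
                          network_edges = path$n_edges)
  if (!is.null(truth)) {
    manifest$truth <- list(support = truth@supportGenes,
                           path = truth@plantedPath)
  }
  writeManifest <- manifest
  writeManifest$stages <- lapply(manifest$stages, function(s) {
    s[setdiff(names(s), c("expression", "result", "solution", "network",
                          "ppi", "truth"))]
  })
  jsonlite::write_json(writeManifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
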