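#' Configure a synthetic study
#'
#' Builds a validated [SimulationConfig-class]. The defaults define the
#' package's reference study conditions: a four-group ordinal phenotype with
#' 8 samples per group (32 in all, emulating a small hippocampal microarray
#' cohort), 60 genes, a planted start-to-end path of 3 intermediate nodes,
#' and a 5-gene regression support with a mean shift of 2 noise-SD per group
#' step. The two plantings are disjoint: support genes are drawn from the
#' off-path genes (seeded), so the path carries the correlation structure,
#' the support carries the group signal, and every other gene is i.i.d.
#' noise. The gene count keeps the exact subnetwork solver's optimality
#' proof to seconds while preserving the small-n / large-p regime.
#'
#' @param nPerGroup samples per group (4 groups).
#' @param nGenes number of genes.
#' @param nSupport number of truly associated genes.
#' @param effectSize per-group-step mean shift in units of \code{noiseSd}.
#' @param pathLength intermediate nodes on the planted start-to-end path.
#' @param pathCorrelation latent-factor loading in (0, 1]; two path genes
#'   have population Pearson correlation \code{pathCorrelation^2}.
#' @param noiseSd residual standard deviation.
#' @param networkModel \code{"preferential-attachment"} or
#'   \code{"erdos-renyi"} background graph.
#' @param attachmentEdges edges added per node (preferential attachment).
#' @param edgeProb edge probability (Erdos-Renyi).
#' @param seed integer seed; every generator output is a pure function of
#'   the configuration, including this seed.
#' @return a \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nGenes = 50, seed = 3)
#' cfg
#' @export
simulationConfig <- function(nPerGroup = 8, nGenes = 60, nSupport = 5,
                             effectSize = 2, pathLength = 3,
                             pathCorrelation = 0.9, noiseSd = 1,
                             networkModel = c("preferential-attachment",
                                              "erdos-renyi"),
                             attachmentEdges = 2, edgeProb = NA_real_,
                             seed = 1) {
  networkModel <- match.arg(networkModel)
  new("SimulationConfig",
      nPerGroup = as.integer(nPerGroup), nGenes = as.integer(nGenes),
      nSupport = as.integer(nSupport), effectSize = as.numeric(effectSize),
      pathLength = as.integer(pathLength),
      pathCorrelation = as.numeric(pathCorrelation),
      noiseSd = as.numeric(noiseSd), networkModel = networkModel,
      attachmentEdges = as.integer(attachmentEdges),
      edgeProb = as.numeric(edgeProb), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: 4 x %d samples, %d genes ",
                     "(support %d, effect %.2g), path length %d ",
                     "(loading %.2g), %s background, seed %d\n"),
              object@nPerGroup, object@nGenes, object@nSupport,
              object@effectSize, object@pathLength, object@pathCorrelation,
              object@networkModel, object@seed))
})

geneIds <- function(n) sprintf("g%0*d", max(3L, nchar(n)), seq_len(n))

## Path nodes occupy the first pathLength + 2 gene ids; support genes are a
## seeded sample of off-path genes, so the two plantings stay disjoint (the
## path carries the correlation structure, the support the group signal,
## everything else is i.i.d. noise).
plantedLayout <- function(config) {
  ids <- geneIds(config@nGenes)
  path <- ids[seq_len(config@pathLength + 2L)]
  pool <- setdiff(ids, path)
  if (config@nSupport > length(pool)) {
    stop("nSupport + pathLength + 2 must be <= nGenes")
  }
  support <- sort(withSeed(stageSeed(config@seed, "graph") + 1L,
                           sample(pool, config@nSupport)))
  list(ids = ids, path = path, support = support,
       start = path[1L], end = path[length(path)])
}

#' Simulate a protein-interaction graph with a planted path
#'
#' Draws a background random graph (preferential attachment or
#' Erdos-Renyi), relabels its vertices by a random permutation of the gene
#' ids, then injects the planted start-to-end path and deduplicates, so the
#' path's edges are guaranteed present whatever the background produced.
#' Each support gene is additionally linked to two (seeded-random) path
#' nodes, emulating transduction factors that sit adjacent to the pathway
#' backbone in the interaction network — the configuration in which fixing
#' them into the subnetwork program is biologically coherent.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements \code{network} (a [GeneNetwork-class]) and
#'   \code{truth} (a [SyntheticTruth-class]).
#' @examples
#' sim <- simulatePPIGraph(simulationConfig(nGenes = 30, seed = 2))
#' sim$truth@plantedPath
#' @export
simulatePPIGraph <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  lay <- plantedLayout(config)
  bg <- withSeed(stageSeed(config@seed, "graph"), {
    g <- switch(config@networkModel,
      "preferential-attachment" = igraph::sample_pa(
        config@nGenes, m = config@attachmentEdges, directed = FALSE),
      "erdos-renyi" = igraph::sample_gnp(config@nGenes, config@edgeProb))
    igraph::V(g)$name <- sample(lay$ids)
    g
  })
  el <- igraph::as_edgelist(bg, names = TRUE)
  pathEdges <- if (length(lay$path) >= 2L) {
    cbind(lay$path[-length(lay$path)], lay$path[-1L])
  } else {
    matrix(character(), ncol = 2L)
  }
  anchorEdges <- if (length(lay$support)) {
    withSeed(stageSeed(config@seed, "graph") + 2L, {
      do.call(rbind, lapply(lay$support, function(u) {
        cbind(u, sample(lay$path, min(2L, length(lay$path))))
      }))
    })
  } else {
    matrix(character(), ncol = 2L)
  }
  ed <- canonicalEdges(c(el[, 1L], pathEdges[, 1L], anchorEdges[, 1L]),
                       c(el[, 2L], pathEdges[, 2L], anchorEdges[, 2L]))
  net <- GeneNetwork(ed, nodes = lay$ids)
  betaTrue <- stats::setNames(rep(0, config@nGenes), lay$ids)
  betaTrue[lay$support] <- config@effectSize * config@noiseSd
  truth <- new("SyntheticTruth",
               supportGenes = lay$support, plantedPath = lay$path,
               plantedEdges = canonicalEdges(pathEdges[, 1L],
                                             pathEdges[, 2L]),
               betaTrue = betaTrue[betaTrue != 0],
               start = lay$start, end = lay$end)
  list(network = net, truth = truth)
}

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(paste0("SyntheticTruth: %d support genes; planted path ",
                     "%s -> ... -> %s (%d nodes)\n"),
              length(object@supportGenes), object@start, object@end,
              length(object@plantedPath)))
})

#' Simulate group-structured expression data
#'
#' Generates a genes-by-samples matrix for the four ordinal phenotype
#' groups. Support genes get mean \code{effectSize * group * noiseSd};
#' planted-path genes share a per-sample latent factor with loading
#' \code{pathCorrelation} plus an independent residual of variance
#' \code{1 - pathCorrelation^2} (so their population pairwise correlation is
#' \code{pathCorrelation^2}); all other genes are i.i.d. Gaussian noise.
#'
#' @param config a [SimulationConfig-class].
#' @param truth the [SyntheticTruth-class] produced from the same config.
#' @return a list with \code{expression} (a
#'   \linkS4class{SummarizedExperiment} whose \code{colData} carries
#'   \code{sample_id}, \code{group} and the centered \code{response}) and
#'   \code{phenotypes} (a plain data frame of \code{sample_id},
#'   \code{group}).
#' @examples
#' cfg <- simulationConfig(nGenes = 20, nPerGroup = 4, seed = 5)
#' sim <- simulatePPIGraph(cfg)
#' dat <- simulateExpression(cfg, sim$truth)
#' dim(SummarizedExperiment::assay(dat$expression))
#' @export
simulateExpression <- function(config, truth) {
  stopifnot(is(config, "SimulationConfig"), is(truth, "SyntheticTruth"))
  validObject(config)
  n <- 4L * config@nPerGroup
  group <- rep(0:3, each = config@nPerGroup)
  sids <- sprintf("s%03d", seq_len(n))
  ids <- geneIds(config@nGenes)
  a <- config@pathCorrelation
  sdn <- config@noiseSd
  X <- withSeed(stageSeed(config@seed, "expression"), {
    f <- stats::rnorm(n)                              # shared latent factor
    M <- matrix(stats::rnorm(config@nGenes * n), config@nGenes, n)
    pathIdx <- match(truth@plantedPath, ids)
    if (length(pathIdx)) {
      Z <- matrix(stats::rnorm(length(pathIdx) * n), length(pathIdx), n)
      M[pathIdx, ] <- a * rep(f, each = length(pathIdx)) +
        sqrt(1 - a^2) * Z
    }
    M <- sdn * M
    supIdx <- match(truth@supportGenes, ids)
    M[supIdx, ] <- M[supIdx, ] +
      config@effectSize * sdn * rep(group, each = length(supIdx))
    M
  })
  dimnames(X) <- list(ids, sids)
  cd <- S4Vectors::DataFrame(sample_id = sids, group = group,
                             response = group - mean(group),
                             row.names = sids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = X), colData = cd,
    metadata = list(standardized = FALSE))
  list(expression = se,
       phenotypes = data.frame(sample_id = sids, group = group,
                               stringsAsFactors = FALSE))
}

#' Write a complete fixture set to disk
#'
#' Emits the expression TSV, phenotype TSV, one edge list per network, the
#' ground-truth JSON, and a manifest (written as \code{manifest.json})
#' listing every file with its dimensions. A fresh read of the fixtures
#' round-trips equal content to printed precision.
#'
#' @param dir output directory (created if needed).
#' @param expression a \code{SummarizedExperiment} from
#'   [simulateExpression()].
#' @param phenotypes the matching phenotype data frame.
#' @param networks a named list of [GeneNetwork-class] objects.
#' @param truth a [SyntheticTruth-class].
#' @return the manifest, invisibly (a list).
#' @export
writeFixtureSet <- function(dir, expression, phenotypes, networks, truth) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(names(networks)) || any(names(networks) == "")) {
    names(networks) <- paste0("network", seq_along(networks))
  }
  paths <- list(expression = file.path(dir, "expression.tsv"),
                phenotypes = file.path(dir, "phenotypes.tsv"),
                truth = file.path(dir, "truth.json"))
  writeExpression(expression, paths$expression)
  utils::write.table(phenotypes, paths$phenotypes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(networks)) {
    p <- file.path(dir, paste0(nm, "_edges.tsv"))
    writeNetwork(networks[[nm]], p)
    paths[[nm]] <- p
  }
  jsonlite::write_json(
    list(support = truth@supportGenes,
         beta_true = as.list(truth@betaTrue),
         path = truth@plantedPath, start = truth@start, end = truth@end),
    paths$truth, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    files = lapply(paths, normalizePath),
    n_genes = nrow(expression), n_samples = ncol(expression),
    networks = lapply(networks, function(net) {
      list(nodes = length(networkNodes(net)),
           edges = nrow(networkEdges(net)))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
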