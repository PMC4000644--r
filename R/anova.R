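#' Per-gene one-way ANOVA prefilter
#'
#' Screens genes by a classical one-way F-test of equal means across the
#' phenotype groups (equal-variance pooling, via
#' \code{stats::oneway.test(var.equal = TRUE)}). The default mode retains
#' genes with p below \code{alpha} — the genes treated as significant by the
#' downstream regression. \code{mode = "literal"} instead removes those
#' genes, kept for audit of the complementary reading of the rule.
#'
#' Genes with zero variance everywhere (F undefined) are dropped with a
#' warning. A gene with zero within-group but positive between-group
#' variance has p = 0 and is retained.
#'
#' @param se a \code{SummarizedExperiment} with \code{group} in its
#'   \code{colData} (see [attachPhenotypes()]).
#' @param alpha significance cutoff (default 0.05).
#' @param mode \code{"retain"} (keep p < alpha) or \code{"literal"}
#'   (remove p < alpha).
#' @return the filtered \code{SummarizedExperiment}, original gene order
#'   preserved, with the per-gene p-value in \code{rowData(x)$anova_p}.
#' @examples
#' cfg <- simulationConfig(nGenes = 30, seed = 9)
#' dat <- simulateExpression(cfg, simulatePPIGraph(cfg)$truth)
#' filtered <- anovaFilter(dat$expression)
#' @export
anovaFilter <- function(se, alpha = 0.05, mode = c("retain", "literal")) {
  mode <- match.arg(mode)
  g <- SummarizedExperiment::colData(se)$group
  if (is.null(g)) stop("colData needs a `group` column; see attachPhenotypes()")
  g <- factor(g)
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop("need >= 2 groups each with >= 2 samples")
  }
  m <- SummarizedExperiment::assay(se, "exprs")
  p <- apply(m, 1L, function(x) {
    if (stats::var(x) == 0) return(NA_real_)    # constant gene: F undefined
    stats::oneway.test(x ~ g, var.equal = TRUE)$p.value
  })
  degenerate <- is.na(p) | is.nan(p)
  if (any(degenerate)) {
    warning(sum(degenerate),
            " gene(s) dropped: degenerate variance, F undefined")
  }
  keep <- !degenerate & if (mode == "retain") p < alpha else p >= alpha
  out <- se[keep, ]
  SummarizedExperiment::rowData(out)$anova_p <- p[keep]
  out
}
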