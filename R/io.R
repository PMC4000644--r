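#' Read a gene-by-sample expression matrix
#'
#' Expects a tab-separated file with a header of sample ids and gene ids in
#' the first column. Genes containing any missing or non-numeric entry are
#' dropped with a warning giving the count; a duplicated gene id or an empty
#' resulting matrix is a hard error.
#'
#' @param path file path.
#' @return a \linkS4class{SummarizedExperiment} with assay \code{exprs};
#'   \code{metadata(x)$standardized} is \code{FALSE}.
#' @export
readExpression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("expression file needs gene ids and >= 1 sample")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(col), numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- apply(vals, 1L, anyNA)
  if (any(bad)) {
    warning(sum(bad), " gene(s) dropped: missing or non-numeric entries")
  }
  vals <- vals[!bad, , drop = FALSE]
  if (nrow(vals) == 0L) stop("no genes left after dropping malformed rows")
  dimnames(vals) <- list(ids[!bad], colnames(df)[-1L])
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = vals),
    metadata = list(standardized = FALSE))
}

writeExpression <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "exprs")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample phenotype table
#'
#' Tab-separated with columns \code{sample_id} and \code{group} (integer
#' ordinal disease stage, 0-3).
#'
#' @param path file path.
#' @return a data frame with \code{sample_id}, \code{group} and the
#'   centered \code{response}.
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("sample_id", "group")
  if (!all(need %in% names(df))) {
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  }
  grp <- suppressWarnings(as.integer(df$group))
  if (anyNA(grp)) stop("non-integer value in `group` column")
  data.frame(sample_id = as.character(df$sample_id), group = grp,
             response = grp - mean(grp), stringsAsFactors = FALSE)
}

#' Attach phenotypes to an expression object
#'
#' Aligns samples by id: expression samples absent from the phenotype table
#' are dropped with a warning, and the response is re-centered on the kept
#' samples.
#'
#' @param se a \code{SummarizedExperiment} from [readExpression()].
#' @param phenotypes a data frame from [readPhenotypes()].
#' @return the \code{SummarizedExperiment} with \code{group} and
#'   \code{response} in its \code{colData}.
#' @export
attachPhenotypes <- function(se, phenotypes) {
  keep <- colnames(se) %in% phenotypes$sample_id
  if (!any(keep)) stop("no expression samples match the phenotype table")
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) without phenotype dropped")
    se <- se[, keep]
  }
  idx <- match(colnames(se), phenotypes$sample_id)
  grp <- phenotypes$group[idx]
  SummarizedExperiment::colData(se)$sample_id <- colnames(se)
  SummarizedExperiment::colData(se)$group <- grp
  SummarizedExperiment::colData(se)$response <- grp - mean(grp)
  se
}

#' Read an undirected edge list
#'
#' Two or three tab-separated columns (\code{gene_a}, \code{gene_b},
#' optional nonnegative \code{weight}); lines starting with \code{#} are
#' comments. Self-loops are discarded, duplicate edges collapsed keeping
#' the maximum weight; a negative or malformed weight is a hard error.
#'
#' @param path file path.
#' @return a [GeneNetwork-class].
#' @export
readNetwork <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(GeneNetwork())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 2L | nc > 3L)) {
    stop("edge list lines must have 2 or 3 tab-separated fields")
  }
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  w <- rep(1, length(a))
  hasW <- nc == 3L
  if (any(hasW)) {
    wRaw <- suppressWarnings(
      as.numeric(vapply(parts[hasW], `[`, "", 3L)))
    if (anyNA(wRaw)) stop("malformed numeric weight in edge list")
    w[hasW] <- wRaw
  }
  if (any(w < 0)) stop("negative edge weights are not allowed")
  GeneNetwork(data.frame(a = a, b = b, weight = w,
                         stringsAsFactors = FALSE))
}

#' Write a network as an edge list
#'
#' Tab-separated \code{gene_a}, \code{gene_b}, \code{weight} with a
#' commented header line, the format [readNetwork()] consumes.
#'
#' @param net a [GeneNetwork-class].
#' @param path output file.
#' @export
writeNetwork <- function(net, path) {
  ed <- networkEdges(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gene_a\tgene_b\tweight", con)
  if (nrow(ed)) {
    writeLines(sprintf("%s\t%s\t%.17g", ed$a, ed$b, ed$weight), con)
  }
  invisible(path)
}

#' Export a solved pathway
#'
#' GraphML output carries a node attribute \code{role} (one of
#' \code{start}, \code{end}, \code{selected_gene}, \code{ilp_added}) and an
#' edge attribute \code{weight}; SIF uses the relation \code{pp}.
#' Re-reading the GraphML (e.g. with \code{igraph::read_graph}) recovers
#' the identical node and edge sets.
#'
#' @param solution a [PathwaySolution-class].
#' @param path output file.
#' @param format \code{"graphml"} or \code{"sif"}.
#' @export
writeSolutionNetwork <- function(solution, path,
                                 format = c("graphml", "sif")) {
  format <- match.arg(format)
  ed <- solution@selectedEdges
  if (format == "sif") {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(ed)) writeLines(sprintf("%s\tpp\t%s", ed$a, ed$b), con)
    lonely <- setdiff(solution@selectedNodes, c(ed$a, ed$b))
    if (length(lonely)) writeLines(lonely, con)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = solution@selectedNodes)
  igraph::V(g)$role <- nodeRoles(solution)[igraph::V(g)$name]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

nodeRoles <- function(solution) {
  roles <- stats::setNames(rep("ilp_added", length(solution@selectedNodes)),
                           solution@selectedNodes)
  roles[intersect(solution@fixedNodes, names(roles))] <- "selected_gene"
  roles[solution@start] <- "start"
  roles[solution@end] <- "end"
  roles
}
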