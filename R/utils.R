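# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

softThreshold <- function(z, gamma) sign(z) * pmax(abs(z) - gamma, 0)

## Evaluate `expr` under a deterministic RNG state and restore the caller's
## stream afterwards, so library functions never perturb user-level draws.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## One seed per pipeline stage, derived from the run seed by a fixed label
## offset; adding a stage never perturbs the draws of earlier stages.
## Result stays below 2^31 - 1.
stageSeed <- function(seed, stage) {
  offsets <- c(graph = 101, expression = 211, cv = 307, pipeline = 401,
               fixtures = 503, instance = 601, weights = 701)
  if (!stage %in% names(offsets)) {
    stop("unknown stage label: ", stage, call. = FALSE)
  }
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + offsets[[stage]]) %%
               2147483629)
}

## Canonicalize an edge table: endpoints as character, a < b within each row,
## rows sorted by (a, b), duplicates collapsed keeping the maximum weight,
## self-loops dropped.
canonicalEdges <- function(a, b, weight = NULL) {
  a <- as.character(a)
  b <- as.character(b)
  if (is.null(weight)) weight <- rep(1, length(a))
  keep <- a != b
  a <- a[keep]; b <- b[keep]; weight <- weight[keep]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    w <- tapply(weight, key, max)
    ord <- order(names(w))
    parts <- strsplit(names(w)[ord], "\r", fixed = TRUE)
    data.frame(a = vapply(parts, `[`, "", 1L),
               b = vapply(parts, `[`, "", 2L),
               weight = as.numeric(w[ord]),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(a = character(), b = character(), weight = numeric(),
               stringsAsFactors = FALSE)
  }
}

## Structured condition for an ILP without any feasible assignment.
infeasibleError <- function(message, nodes = character()) {
  structure(class = c("pathSTN_infeasible", "error", "condition"),
            list(message = message, call = NULL, nodes = nodes))
}
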