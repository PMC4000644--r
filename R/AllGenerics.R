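#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @export
setGeneric("selectedGenes",
           function(x, tolerance = 1e-8) standardGeneric("selectedGenes"))

#' @export
setGeneric("pathwayNodes", function(x) standardGeneric("pathwayNodes"))

#' @export
setGeneric("pathwayEdges", function(x) standardGeneric("pathwayEdges"))

#' @export
setGeneric("pathwayComponents", function(x) standardGeneric("pathwayComponents"))
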