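NULL

#' @export
setGeneric("intensities", function(x, ...) standardGeneric("intensities"))

#' @export
setGeneric("omicsScale", function(x) standardGeneric("omicsScale"))

#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @export
setGeneric("selectionProportions",
           function(x) standardGeneric("selectionProportions"))

#' @export
setGeneric("adjacency", function(x, ...) standardGeneric("adjacency"))

#' @export
setGeneric("edgeList", function(x, ...) standardGeneric("edgeList"))

#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @export
setGeneric("medoids", function(x) standardGeneric("medoids"))

#' @export
setGeneric("comembership", function(x) standardGeneric("comembership"))
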