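#' @rdname extractSegments
#' @export
setGeneric("extractSegments", function(x, ...) standardGeneric("extractSegments"))

#' @rdname totalDendriticLength
#' @export
setGeneric("totalDendriticLength", function(x, ...) standardGeneric("totalDendriticLength"))

#' @rdname terminalCount
#' @export
setGeneric("terminalCount", function(x, ...) standardGeneric("terminalCount"))

#' @rdname spatialVolume
#' @export
setGeneric("spatialVolume", function(x, ...) standardGeneric("spatialVolume"))

#' @rdname summarizeMorphometry
#' @export
setGeneric("summarizeMorphometry", function(x, ...) standardGeneric("summarizeMorphometry"))

#' @rdname shollProfile
#' @export
setGeneric("shollProfile", function(x, ...) standardGeneric("shollProfile"))

#' @rdname neuronTree-accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname neuronTree-accessors
#' @export
setGeneric("somaId", function(x) standardGeneric("somaId"))

#' @rdname neuronTree-accessors
#' @export
setGeneric("somaPosition", function(x) standardGeneric("somaPosition"))

#' @rdname neuronTree-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname neuronTree-accessors
#' @export
setGeneric("specimenMeta", function(x) standardGeneric("specimenMeta"))

#' @rdname neuronTree-accessors
#' @export
setGeneric("specimenMeta<-", function(x, value) standardGeneric("specimenMeta<-"))

#' @rdname shollProfile-accessors
#' @export
setGeneric("shellRadii", function(x) standardGeneric("shellRadii"))

#' @rdname shollProfile-accessors
#' @export
setGeneric("intersectionCounts", function(x) standardGeneric("intersectionCounts"))
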