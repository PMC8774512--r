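#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))
#' @rdname accessors
#' @export
setGeneric("sliceData", function(x) standardGeneric("sliceData"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @rdname accessors
#' @export
setGeneric("compartment", function(x) standardGeneric("compartment"))

#' @rdname detectionMetrics
#' @export
setGeneric("recall", function(counts) standardGeneric("recall"))
#' @rdname detectionMetrics
#' @export
setGeneric("precision", function(counts) standardGeneric("precision"))
#' @rdname detectionMetrics
#' @export
setGeneric("accuracy", function(counts) standardGeneric("accuracy"))

#' @rdname overlapMetrics
#' @export
setGeneric("diceScore", function(x, ...) standardGeneric("diceScore"))
#' @rdname overlapMetrics
#' @export
setGeneric("similarityIndex", function(x, ...) standardGeneric("similarityIndex"))
#' @rdname overlapMetrics
#' @export
setGeneric("truePositiveRate", function(x, ...) standardGeneric("truePositiveRate"))
#' @rdname overlapMetrics
#' @export
setGeneric("falsePositiveRate", function(x, ...) standardGeneric("falsePositiveRate"))
#' @rdname overlapMetrics
#' @export
setGeneric("falseNegativeRate", function(x, ...) standardGeneric("falseNegativeRate"))

#' @rdname unetSpec
#' @export
setGeneric("countParameters", function(spec) standardGeneric("countParameters"))
#' @rdname unetSpec
#' @export
setGeneric("countConvLayers", function(spec) standardGeneric("countConvLayers"))
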