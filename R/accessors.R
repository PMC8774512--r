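#' @include AllGenerics.R
NULL

#' Construct an MRISequence
#'
#' @param caseId case identifier.
#' @param data 3-d array `(H, W, nSlices)` of slice intensities, or a list of
#'   equally sized matrices (stacked in order).
#' @param spacing voxel size `(row_mm, col_mm, slice_mm)` in millimetres.
#' @return an [MRISequence-class] object.
#' @examples
#' seq <- MRISequence("case1", array(0, c(8, 8, 3)))
#' nSlices(seq)
#' @export
MRISequence <- function(caseId, data, spacing = c(1, 1, 1)) {
  if (is.list(data)) data <- simplify2array(data)
  new("MRISequence", caseId = as.character(caseId), data = data,
      spacing = as.numeric(spacing))
}

#' Construct a MaskSequence
#'
#' @param caseId case identifier of the paired sequence.
#' @param compartment one of `"femur"`, `"tibia"`, `"patella"`, `"whole"`.
#' @param data 3-d array of 0/1 values (logical arrays are coerced).
#' @return a [MaskSequence-class] object.
#' @export
MaskSequence <- function(caseId, compartment, data) {
  if (is.list(data)) data <- simplify2array(data)
  data <- array(as.numeric(data), dim(data))  # one storage type for all masks
  new("MaskSequence", caseId = as.character(caseId),
      compartment = match.arg(compartment, .COMPARTMENTS), data = data)
}

#' Accessors for slice-stack objects
#'
#' `caseId`, `sliceData`, `spacing`, `nSlices` and `compartment` extract the
#' corresponding components of [MRISequence-class] and [MaskSequence-class]
#' objects.
#'
#' @param x an `MRISequence` or `MaskSequence`.
#' @return the component (`sliceData` returns the 3-d array).
#' @name accessors
NULL

#' @rdname accessors
setMethod("caseId", "MRISequence", function(x) x@caseId)
#' @rdname accessors
setMethod("caseId", "MaskSequence", function(x) x@caseId)
#' @rdname accessors
setMethod("sliceData", "MRISequence", function(x) x@data)
#' @rdname accessors
setMethod("sliceData", "MaskSequence", function(x) x@data)
#' @rdname accessors
setMethod("spacing", "MRISequence", function(x) x@spacing)
#' @rdname accessors
setMethod("nSlices", "MRISequence", function(x) dim(x@data)[3])
#' @rdname accessors
setMethod("nSlices", "MaskSequence", function(x) dim(x@data)[3])
#' @rdname accessors
setMethod("compartment", "MaskSequence", function(x) x@compartment)

setMethod("show", "MRISequence", function(object) {
  d <- dim(object@data)
  cat(sprintf("MRISequence '%s': %d slices of %dx%d, spacing (%g, %g, %g) mm\n",
              object@caseId, d[3], d[1], d[2],
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "MaskSequence", function(object) {
  d <- dim(object@data)
  cat(sprintf("MaskSequence '%s' [%s]: %d slices of %dx%d, %d positive voxels\n",
              object@caseId, object@compartment, d[3], d[1], d[2],
              sum(object@data)))
})

setMethod("show", "CaseSplit", function(object) {
  cat(sprintf("CaseSplit: %d train / %d val / %d test cases\n",
              length(object@trainIds), length(object@valIds),
              length(object@testIds)))
})

setMethod("show", "UNetSpec", function(object) {
  cat(sprintf(
    "UNetSpec: in=%d out=%d base=%d depth=%d input=%dx%d (%s head)\n  %s conv layers, %s parameters\n",
    object@inChannels, object@outChannels, object@baseWidth, object@depth,
    object@inputSize, object@inputSize, object@finalActivation,
    format(countConvLayers(object), big.mark = ","),
    format(countParameters(object), big.mark = ",")))
})

setMethod("show", "UNetModel", function(object) {
  cat("Modified U-net model\n")
  show(object@spec)
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d (n=%d slices)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})

setMethod("show", "OverlapCounts", function(object) {
  cat(sprintf("OverlapCounts: |Sg|=%g |Sm|=%g |Sg n Sm|=%g\n",
              object@nG, object@nM, object@nInter))
})

setMethod("show", "SlicePresence", function(object) {
  cat(sprintf("SlicePresence: %d/%d positive slices, interval [%s, %s]\n",
              sum(object@presence), length(object@presence),
              object@firstIndex, object@lastIndex))
})

setMethod("show", "BonePipeline", function(object) {
  cat(sprintf(
    "BonePipeline: detectors [%s], segmenters [%s]\n  detection size %d, threshold %g, minArea %d, selection '%s'\n",
    paste(names(object@detectors), collapse = ", "),
    paste(names(object@segmenters), collapse = ", "),
    object@detectionSize, object@probThreshold, object@minArea,
    object@selectionMode))
})
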