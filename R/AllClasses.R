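#' @import methods
NULL

.COMPARTMENTS <- c("femur", "tibia", "patella", "whole")

#' MRISequence: one knee MRI case as an ordered 2D slice stack
#'
#' Container for a single 3D MRI case stored as an ordered stack of 2D
#' intensity slices, together with the voxel spacing in millimetres.
#' The array layout is `(height, width, slice)`.
#'
#' @slot caseId character(1) case identifier.
#' @slot data numeric 3-d array `(H, W, nSlices)` of slice intensities.
#' @slot spacing numeric(3) voxel size `(row_mm, col_mm, slice_mm)`, all > 0.
#' @export
setClass("MRISequence",
  representation(caseId = "character", data = "array", spacing = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3-d array (H, W, nSlices)")
    if (d[3] < 1L) return("stack must contain at least one slice")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0)) return("spacing must be 3 positive numbers")
    if (length(object@caseId) != 1L) return("caseId must be a single string")
    TRUE
  }
)

#' MaskSequence: per-compartment binary mask stack
#'
#' Binary (0/1) mask stack aligned slice-for-slice with an [MRISequence].
#' `compartment` names the knee bone the mask delineates: femur, tibia,
#' patella, or their union ("whole").
#'
#' @slot caseId character(1) case identifier of the paired sequence.
#' @slot compartment character(1), one of `"femur"`, `"tibia"`, `"patella"`,
#'   `"whole"`.
#' @slot data numeric/integer 3-d array `(H, W, nSlices)` with values in
#'   \{0, 1\}.
#' @export
setClass("MaskSequence",
  representation(caseId = "character", compartment = "character", data = "array"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3-d array (H, W, nSlices)")
    if (!object@compartment %in% .COMPARTMENTS)
      return(sprintf("compartment must be one of %s",
                     paste(.COMPARTMENTS, collapse = ", ")))
    v <- object@data
    if (any(v != 0 & v != 1)) return("mask values must all be 0 or 1")
    TRUE
  }
)

#' CaseSplit: case-level train/validation/test partition
#'
#' Disjoint sets of case identifiers. Splitting is done at the case level so
#' that all slices of one scan travel together, never across sets.
#'
#' @slot trainIds,valIds,testIds character vectors of case ids.
#' @export
setClass("CaseSplit",
  representation(trainIds = "character", valIds = "character",
                 testIds = "character"),
  validity = function(object) {
    all3 <- c(object@trainIds, object@valIds, object@testIds)
    if (anyDuplicated(all3)) return("train/val/test ids must be disjoint")
    TRUE
  }
)

#' PhantomConfig: parameters of the synthetic knee phantom generator
#'
#' Describes a family of synthetic knee-like MRI cases: stack length, image
#' size, per-compartment slice-appearance ranges and ellipse shape parameters,
#' bone/background intensities and additive Gaussian noise.
#'
#' @slot nCases integer(1) number of cases the configuration describes.
#' @slot nSlices integer(1) slices per case (default 160).
#' @slot imageSize integer(1) square slice size in pixels (default 384).
#' @slot compartments named list (femur/tibia/patella); each entry holds
#'   `startRange`, `endRange` (inclusive 1-based slice windows the appearance
#'   interval is drawn from) and normalised shape parameters `cx`, `cy`, `rx`,
#'   `ry` (2-vectors, fractions of image size) plus `drift` (max centre drift).
#' @slot noiseSd numeric(1) additive Gaussian noise sd (intensity units).
#' @slot boneIntensity,backgroundIntensity numeric(1) in \[0, 1\].
#' @slot seed integer(1) root seed; case `i` uses stream `seed + i`.
#' @export
setClass("PhantomConfig",
  representation(nCases = "integer", nSlices = "integer", imageSize = "integer",
                 compartments = "list", noiseSd = "numeric",
                 boneIntensity = "numeric", backgroundIntensity = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nCases < 1L) return("nCases must be >= 1")
    if (object@nSlices < 1L || object@imageSize < 8L)
      return("nSlices must be >= 1 and imageSize >= 8")
    if (object@noiseSd < 0) return("noiseSd must be non-negative")
    for (nm in names(object@compartments)) {
      cp <- object@compartments[[nm]]
      if (min(cp$startRange) < 1L || max(cp$endRange) > object@nSlices)
        return(sprintf("%s: slice ranges must lie in 1..nSlices", nm))
      if (max(cp$startRange) >= min(cp$endRange))
        return(sprintf("%s: start range must end before end range begins", nm))
    }
    TRUE
  }
)

#' UNetSpec: architecture hyper-parameters of the modified U-net
#'
#' Fully determines the network: channel widths, depth (number of resolution
#' levels including the bottleneck), input size and the sigmoid head. The
#' closed-form parameter count [countParameters()] is a function of this spec
#' alone.
#'
#' @slot inChannels,outChannels integer(1), default 1 each.
#' @slot baseWidth integer(1) channels at the highest resolution (default 64).
#' @slot depth integer(1) levels including the bottleneck (default 5).
#' @slot inputSize integer(1) square input size in pixels; must be divisible
#'   by `2^(depth - 1)`.
#' @slot finalActivation character(1), `"sigmoid"`.
#' @export
setClass("UNetSpec",
  representation(inChannels = "integer", outChannels = "integer",
                 baseWidth = "integer", depth = "integer",
                 inputSize = "integer", finalActivation = "character"),
  validity = function(object) {
    if (object@baseWidth < 1L) return("baseWidth must be >= 1")
    if (object@depth < 2L) return("depth must be >= 2")
    if (object@inputSize %% (2L^(object@depth - 1L)) != 0L)
      return(sprintf("inputSize %d not divisible by 2^(depth-1) = %d",
                     object@inputSize, 2L^(object@depth - 1L)))
    if (!identical(object@finalActivation, "sigmoid"))
      return("finalActivation must be \"sigmoid\"")
    TRUE
  }
)

#' UNetModel: an instantiated modified U-net
#'
#' Holds a [UNetSpec] together with the weight tensors (flat named list of
#' matrices/vectors in the layout the convolution kernels expect) and the seed
#' used for initialisation.
#'
#' @slot spec a [UNetSpec].
#' @slot params named list of weight matrices and bias vectors.
#' @slot seed integer(1) initialisation seed.
#' @export
setClass("UNetModel",
  representation(spec = "UNetSpec", params = "list", seed = "integer"))

#' TrainConfig: optimiser and stopping schedule
#'
#' Adam learning rate, mini-batch size, epoch cap, early-stopping patience,
#' loss and monitored validation metric. Defaults follow the reference
#' schedule for the full-scale networks: learning rate 1e-5, batch 16, at most
#' 300 epochs, patience 35 epochs without improvement.
#'
#' @slot learningRate numeric(1) > 0.
#' @slot batchSize integer(1) >= 1.
#' @slot maxEpochs integer(1).
#' @slot patience integer(1) < maxEpochs.
#' @slot loss character(1), `"soft_dice"` or `"binary_cross_entropy"`.
#' @slot monitor character(1), `"val_dice"` or `"val_accuracy"`.
#' @slot seed integer(1) shuffling/initialisation seed.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 maxEpochs = "integer", patience = "integer",
                 loss = "character", monitor = "character", seed = "integer"),
  validity = function(object) {
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@patience >= object@maxEpochs)
      return("patience must be smaller than maxEpochs")
    if (!object@loss %in% c("soft_dice", "binary_cross_entropy"))
      return("loss must be soft_dice or binary_cross_entropy")
    if (!object@monitor %in% c("val_dice", "val_accuracy"))
      return("monitor must be val_dice or val_accuracy")
    TRUE
  }
)

#' ConfusionCounts: slice-level detection confusion
#'
#' TP/TN/FP/FN slice counts for the bone-presence detection task. A slice is a
#' true negative only when both the ground truth and the model output carry no
#' bone at all (both masks all-black).
#'
#' @slot tp,tn,fp,fn non-negative integer slice counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", tn = "integer", fp = "integer", fn = "integer"),
  validity = function(object) {
    v <- c(object@tp, object@tn, object@fp, object@fn)
    if (any(is.na(v)) || any(v < 0L)) return("counts must be non-negative")
    TRUE
  }
)

#' OverlapCounts: pooled pixel-set sizes for one case
#'
#' Sizes of the ground-truth bone pixel set Sg, the predicted set Sm and their
#' intersection, pooled over every slice of a case so the compartment is
#' scored as one 3D object.
#'
#' @slot nG,nM,nInter numeric(1) pixel counts `|Sg|`, `|Sm|`, `|Sg n Sm|`.
#' @export
setClass("OverlapCounts",
  representation(nG = "numeric", nM = "numeric", nInter = "numeric"),
  validity = function(object) {
    if (object@nG < 0 || object@nM < 0 || object@nInter < 0)
      return("counts must be non-negative")
    if (object@nInter > min(object@nG, object@nM) + 1e-9)
      return("intersection cannot exceed either set")
    TRUE
  }
)

#' SlicePresence: per-slice bone-presence decision for one case
#'
#' Logical presence vector (one entry per slice, 1-based indices) with the
#' first and last positive slice, or `NA` when no slice is positive.
#'
#' @slot presence logical vector, length = number of slices.
#' @slot firstIndex,lastIndex integer(1) or `NA_integer_`.
#' @export
setClass("SlicePresence",
  representation(presence = "logical", firstIndex = "integer",
                 lastIndex = "integer"),
  validity = function(object) {
    if (any(object@presence)) {
      if (is.na(object@firstIndex) || is.na(object@lastIndex) ||
          object@firstIndex > object@lastIndex)
        return("firstIndex must be <= lastIndex when any slice is positive")
    } else if (!is.na(object@firstIndex) || !is.na(object@lastIndex)) {
      return("indices must be NA when no slice is positive")
    }
    TRUE
  }
)

#' BonePipeline: detection + segmentation models for the automatic pipeline
#'
#' Bundles the slice-presence detector(s) and the per-compartment segmentation
#' model(s), plus the decision thresholds. A model may be a [UNetModel] or any
#' function mapping a `(H, W, 1, N)` image batch to a probability batch of the
#' same shape (used for oracle models in testing).
#'
#' @slot detectors named list of detection models; either one entry per
#'   compartment or a single entry (used for all compartments).
#' @slot segmenters named list of segmentation models, names from
#'   femur/tibia/patella/whole.
#' @slot detectionSize integer(1) square size slices are resized to before
#'   detection.
#' @slot probThreshold numeric(1) pixel probability threshold (default 0.5).
#' @slot minArea integer(1) minimum positive-pixel count for a positive slice.
#' @slot selectionMode character(1), `"per_slice"` or `"fill_range"`.
#' @export
setClass("BonePipeline",
  representation(detectors = "list", segmenters = "list",
                 detectionSize = "integer", probThreshold = "numeric",
                 minArea = "integer", selectionMode = "character"),
  validity = function(object) {
    if (!length(object@segmenters)) return("need at least one segmenter")
    if (!all(names(object@segmenters) %in% .COMPARTMENTS))
      return("segmenter names must be compartments")
    if (!object@selectionMode %in% c("per_slice", "fill_range"))
      return("selectionMode must be per_slice or fill_range")
    if (object@probThreshold <= 0 || object@probThreshold >= 1)
      return("probThreshold must be in (0, 1)")
    if (object@minArea < 1L) return("minArea must be >= 1")
    TRUE
  }
)
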