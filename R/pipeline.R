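#' @include metrics.R volume_io.R training.R
NULL

#' Bundle detection and segmentation models into a pipeline
#'
#' @param detectors a single detection model or a named list (one per
#'   compartment, or one entry applied to all). Models are [UNetModel-class]
#'   objects or functions mapping an image batch to a probability batch.
#' @param segmenters named list of segmentation models (names among femur,
#'   tibia, patella, whole).
#' @param detectionSize square size slices are resized to for detection
#'   (default: the detector's `inputSize` when it is a [UNetModel-class]).
#' @param probThreshold pixel probability threshold (default 0.5).
#' @param minArea minimum count of positive pixels for a positive slice
#'   (default 1).
#' @param selectionMode `"per_slice"` (default; segment exactly the positive
#'   slices) or `"fill_range"` (segment every slice between the first and last
#'   positive slice).
#' @return a [BonePipeline-class].
#' @export
bonePipeline <- function(detectors, segmenters, detectionSize = NULL,
                         probThreshold = 0.5, minArea = 1L,
                         selectionMode = c("per_slice", "fill_range")) {
  if (!is.list(detectors) || is.function(detectors))
    detectors <- list(whole = detectors)
  if (is.null(detectionSize)) {
    first <- detectors[[1]]
    if (!is(first, "UNetModel"))
      stop("detectionSize must be given when detectors are not UNetModels")
    detectionSize <- first@spec@inputSize
  }
  new("BonePipeline", detectors = detectors, segmenters = segmenters,
      detectionSize = as.integer(detectionSize),
      probThreshold = as.numeric(probThreshold), minArea = as.integer(minArea),
      selectionMode = match.arg(selectionMode))
}

.slicesToBatch <- function(arr, indices = NULL) {
  if (is.null(indices)) indices <- seq_len(dim(arr)[3])
  array(arr[, , indices], c(dim(arr)[1], dim(arr)[2], 1L, length(indices)))
}

.presence <- function(positives) {
  pos <- which(positives)
  new("SlicePresence", presence = as.logical(positives),
      firstIndex = if (length(pos)) min(pos) else NA_integer_,
      lastIndex = if (length(pos)) max(pos) else NA_integer_)
}

#' Detect the slices in which bone appears
#'
#' Every slice of a preprocessed (cropped, normalised) sequence is resized to
#' the detection resolution and passed through the detection network. A slice
#' is positive iff at least `minArea` output pixels reach `probThreshold`; an
#' all-black output map means "no bone". The first and last positive slices
#' delimit the bone interval.
#'
#' @param model detection model ([UNetModel-class] or probability function).
#' @param seq a preprocessed [MRISequence-class].
#' @param probThreshold pixel probability threshold in (0, 1), default 0.5.
#' @param minArea minimum positive-pixel count, default 1.
#' @param detectionSize resize target; defaults to the model's `inputSize`
#'   (functions: no resizing).
#' @return a [SlicePresence-class].
#' @export
detectBoneSlices <- function(model, seq, probThreshold = 0.5, minArea = 1L,
                             detectionSize = NULL) {
  stopifnot(is(seq, "MRISequence"))
  if (probThreshold <= 0 || probThreshold >= 1)
    stop("probThreshold must be in (0, 1)")
  x <- sliceData(seq)
  if (is.null(detectionSize) && is(model, "UNetModel"))
    detectionSize <- model@spec@inputSize
  if (!is.null(detectionSize) && any(dim(x)[1:2] != detectionSize)) {
    small <- vapply(seq_len(dim(x)[3]),
                    function(k) resizeGrid(x[, , k], detectionSize,
                                           "intensity"),
                    matrix(0, detectionSize, detectionSize))
    x <- small
  }
  prob <- predictProb(model, .slicesToBatch(x))
  positives <- vapply(seq_len(dim(prob)[4]), function(i)
    sum(prob[, , , i] >= probThreshold) >= minArea, logical(1))
  .presence(positives)
}

#' Select the slices to segment
#'
#' `per_slice` returns exactly the positive slices; `fill_range` returns every
#' index between the first and last positive slice inclusive (the bone
#' interval). An empty presence yields an empty selection in both modes.
#'
#' @param presence a [SlicePresence-class].
#' @param mode `"per_slice"` or `"fill_range"`.
#' @return sorted integer vector of slice indices (1-based).
#' @export
selectSlices <- function(presence, mode = c("per_slice", "fill_range")) {
  stopifnot(is(presence, "SlicePresence"))
  mode <- match.arg(mode)
  if (!any(presence@presence)) return(integer(0))
  if (mode == "per_slice") which(presence@presence)
  else seq(presence@firstIndex, presence@lastIndex)
}

#' Segment the selected slices
#'
#' Runs the segmentation network on the selected slices at full resolution and
#' binarises the probability maps at `probThreshold`; unselected slices are
#' emitted as all-zero masks (a discarded slice carries no bone). The output
#' stack always has the same length as the input stack.
#'
#' @param model segmentation model ([UNetModel-class] or probability
#'   function).
#' @param seq a preprocessed [MRISequence-class] at segmentation resolution.
#' @param indices slice indices to segment (subset of `1..nSlices`).
#' @param probThreshold binarisation threshold, default 0.5.
#' @param compartment compartment label for the output mask.
#' @return a [MaskSequence-class].
#' @export
segmentSlices <- function(model, seq, indices, probThreshold = 0.5,
                          compartment = "whole") {
  stopifnot(is(seq, "MRISequence"))
  x <- sliceData(seq)
  n <- dim(x)[3]
  indices <- as.integer(indices)
  if (length(indices) && (min(indices) < 1L || max(indices) > n))
    stop("slice index out of range")
  out <- array(0, dim(x))
  if (length(indices)) {
    prob <- predictProb(model, .slicesToBatch(x, indices))
    out[, , indices] <- (prob[, , 1, ] >= probThreshold) + 0
  }
  MaskSequence(caseId(seq), compartment, out)
}

#' Combine per-compartment masks into a whole-knee mask
#'
#' The whole-knee mask is the voxelwise union of the compartment masks. When
#' per-voxel probabilities are supplied, a label map is also emitted in which
#' overlapping predictions are resolved by the highest model probability (ties
#' broken in the fixed order femur > tibia > patella); otherwise overlaps are
#' resolved by that fixed order alone.
#'
#' @param masks named list of aligned [MaskSequence-class] objects (femur,
#'   tibia, patella).
#' @param rule combination rule; only `"union"` is defined.
#' @param probs optional named list of probability arrays aligned with the
#'   masks.
#' @return list with `whole` (a [MaskSequence-class]) and `labels` (integer
#'   array, 0 = background, then 1 = femur, 2 = tibia, 3 = patella).
#' @export
combineCompartments <- function(masks, rule = "union", probs = NULL) {
  rule <- match.arg(rule, "union")
  order <- intersect(c("femur", "tibia", "patella"), names(masks))
  if (!length(order)) stop("masks must be named by compartment")
  dims <- lapply(masks[order], function(m) dim(sliceData(m)))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("compartment masks are misaligned")
  d <- dims[[1]]
  union <- array(0, d)
  labels <- array(0L, d)
  bestProb <- array(-Inf, d)
  for (i in seq_along(order)) {
    m <- sliceData(masks[[order[i]]]) > 0.5
    union[m] <- 1
    pr <- if (!is.null(probs) && !is.null(probs[[order[i]]]))
      probs[[order[i]]] else array(1, d)
    take <- m & (pr > bestProb)   # strict: earlier compartments win ties
    labels[take] <- i
    bestProb[take] <- pr[take]
  }
  list(whole = MaskSequence(caseId(masks[[order[1]]]), "whole", union),
       labels = labels)
}

.detectorFor <- function(pipeline, comp) {
  if (!is.null(pipeline@detectors[[comp]])) pipeline@detectors[[comp]]
  else pipeline@detectors[[1]]
}

#' Run the fully automatic pipeline on one sequence
#'
#' Reproduces the automatic flow end to end with no human input: crop a
#' 16-pixel border if the input is still at acquisition size (any margin that
#' reconciles the input with the segmentation resolution is applied),
#' normalise intensities to \[0, 1\], detect the bone slices per compartment,
#' select slices (`per_slice` or `fill_range`), and segment the selected
#' slices at full resolution.
#'
#' @param pipeline a [BonePipeline-class].
#' @param seq an [MRISequence-class], raw (e.g. 384x384) or already cropped.
#' @param normalize normalise intensities first (default TRUE).
#' @return list with `masks` (named list of [MaskSequence-class], one per
#'   segmenter), `presence` (named list of [SlicePresence-class]) and, when
#'   all three compartments are segmented, `combined` (see
#'   [combineCompartments()]).
#' @export
runPipeline <- function(pipeline, seq, normalize = TRUE) {
  stopifnot(is(pipeline, "BonePipeline"), is(seq, "MRISequence"))
  segInput <- dim(sliceData(seq))[1:2]
  firstSeg <- pipeline@segmenters[[1]]
  if (is(firstSeg, "UNetModel")) {
    target <- firstSeg@spec@inputSize
    if (any(segInput != target)) {
      margin <- (segInput[1] - target) / 2
      if (segInput[1] != segInput[2] || margin != round(margin) || margin < 0)
        stop(sprintf("cannot reconcile %dx%d input with %dx%d segmentation",
                     segInput[1], segInput[2], target, target))
      seq <- cropBorders(seq, as.integer(margin))
    }
  }
  if (normalize) seq <- normalizeIntensity(seq)
  masks <- list()
  presence <- list()
  probs <- list()
  for (comp in names(pipeline@segmenters)) {
    det <- .detectorFor(pipeline, comp)
    pres <- detectBoneSlices(det, seq, pipeline@probThreshold,
                             pipeline@minArea,
                             detectionSize = if (is(det, "UNetModel"))
                               det@spec@inputSize else pipeline@detectionSize)
    idx <- selectSlices(pres, pipeline@selectionMode)
    masks[[comp]] <- segmentSlices(pipeline@segmenters[[comp]], seq, idx,
                                   pipeline@probThreshold, comp)
    presence[[comp]] <- pres
  }
  out <- list(masks = masks, presence = presence)
  if (all(c("femur", "tibia", "patella") %in% names(masks)))
    out$combined <- combineCompartments(masks[c("femur", "tibia", "patella")])
  out
}

.truthPresence <- function(mask) {
  m <- sliceData(mask)
  vapply(seq_len(dim(m)[3]), function(k) any(m[, , k] > 0.5), logical(1))
}

#' Evaluate the pipeline on a dataset with ground truth
#'
#' Runs the pipeline on every case and scores each compartment at the case
#' level. With `detectionSource = "automatic"` the full flow is used and the
#' slice-level detection confusion is returned alongside the segmentation
#' report; with `"manual"` the ground-truth presence vectors replace the
#' detection model (the ablation mode), making the result independent of the
#' detector.
#'
#' @param cases list of cases; each case is a list with `sequence`
#'   ([MRISequence-class]) and `masks` (named list of ground-truth
#'   [MaskSequence-class], covering every segmented compartment).
#' @param pipeline a [BonePipeline-class].
#' @param detectionSource `"automatic"` or `"manual"`.
#' @param spacing voxel spacing for volume estimation; default: each
#'   sequence's own spacing.
#' @param normalize normalise intensities (default TRUE).
#' @return list with `report` (see [evalReport()]) and `confusion` (named list
#'   of [ConfusionCounts-class] per compartment; `NULL` in manual mode).
#' @export
evaluatePipeline <- function(cases, pipeline,
                             detectionSource = c("automatic", "manual"),
                             spacing = NULL, normalize = TRUE) {
  detectionSource <- match.arg(detectionSource)
  rows <- list()
  confusion <- list()
  for (cs in cases) {
    seq <- cs$sequence
    if (is.null(cs$masks)) stop("every case needs ground-truth masks")
    sp <- spacing %||% spacing(seq)
    segInput <- dim(sliceData(seq))[1:2]
    firstSeg <- pipeline@segmenters[[1]]
    if (is(firstSeg, "UNetModel")) {
      target <- firstSeg@spec@inputSize
      if (any(segInput != target)) {
        margin <- as.integer((segInput[1] - target) / 2)
        seq <- cropBorders(seq, margin)
        cs$masks <- lapply(cs$masks, cropBorders, margin = margin)
      }
    }
    if (normalize) seq <- normalizeIntensity(seq)
    for (comp in names(pipeline@segmenters)) {
      gt <- cs$masks[[comp]]
      if (is.null(gt)) stop(sprintf("case '%s' lacks ground truth for '%s'",
                                    caseId(seq), comp))
      truthPres <- .truthPresence(gt)
      if (detectionSource == "automatic") {
        det <- .detectorFor(pipeline, comp)
        pres <- detectBoneSlices(det, seq, pipeline@probThreshold,
                                 pipeline@minArea,
                                 detectionSize = if (is(det, "UNetModel"))
                                   det@spec@inputSize else
                                   pipeline@detectionSize)
        confusion[[comp]] <- c(confusion[[comp]],
                               confusionFromPresence(pres@presence, truthPres))
      } else {
        pres <- .presence(truthPres)
      }
      idx <- selectSlices(pres, pipeline@selectionMode)
      predMask <- segmentSlices(pipeline@segmenters[[comp]], seq, idx,
                                pipeline@probThreshold, comp)
      o <- poolOverlap(gt, predMask)
      rows[[length(rows) + 1L]] <- data.frame(
        caseId = caseId(seq), compartment = comp,
        dice = diceScore(o), si = similarityIndex(o),
        tpr = truePositiveRate(o), fpr = falsePositiveRate(o),
        fnr = falseNegativeRate(o),
        volumeGt = boneVolume(gt, sp), volumePred = boneVolume(predMask, sp),
        degenerate = (o@nG + o@nM == 0), stringsAsFactors = FALSE)
    }
  }
  report <- evalReport(do.call(rbind, rows))
  conf <- if (detectionSource == "automatic")
    lapply(confusion, sumConfusion) else NULL
  list(report = report, confusion = conf)
}
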