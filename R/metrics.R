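#' @include accessors.R
NULL

#' Slice-level detection confusion counts
#'
#' Tallies TP/TN/FP/FN over per-slice presence decisions. A slice is TP when
#' bone exists in the ground truth and is detected; TN when neither ground
#' truth nor model output carries bone (both masks all-black); FP when bone is
#' detected but absent from the truth; FN when bone is present but missed.
#'
#' @param pred,truth logical vectors of equal length, one entry per slice.
#' @return a [ConfusionCounts-class].
#' @export
confusionFromPresence <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must have equal lengths")
  new("ConfusionCounts",
      tp = sum(pred & truth), tn = sum(!pred & !truth),
      fp = sum(pred & !truth), fn = sum(!pred & truth))
}

#' Combine confusion counts
#' @param ... [ConfusionCounts-class] objects.
#' @return their elementwise sum as a [ConfusionCounts-class].
#' @export
sumConfusion <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && is.list(cs[[1]]) && !is(cs[[1]], "ConfusionCounts"))
    cs <- cs[[1]]
  new("ConfusionCounts",
      tp = sum(vapply(cs, function(c) c@tp, integer(1))),
      tn = sum(vapply(cs, function(c) c@tn, integer(1))),
      fp = sum(vapply(cs, function(c) c@fp, integer(1))),
      fn = sum(vapply(cs, function(c) c@fn, integer(1))))
}

#' Detection metrics: recall, precision, accuracy
#'
#' Recall (sensitivity) `TP / (TP + FN)`, precision `TP / (TP + FP)` and
#' overall accuracy `100 * (TP + TN) / (TP + TN + FP + FN)` (a percentage).
#' A zero denominator yields `NA` (undefined-metric sentinel), never an error.
#'
#' @param counts a [ConfusionCounts-class].
#' @return scalar metric value, or `NA` when undefined.
#' @name detectionMetrics
NULL

#' @rdname detectionMetrics
setMethod("recall", "ConfusionCounts", function(counts) {
  d <- counts@tp + counts@fn
  if (d == 0L) NA_real_ else counts@tp / d
})

#' @rdname detectionMetrics
setMethod("precision", "ConfusionCounts", function(counts) {
  d <- counts@tp + counts@fp
  if (d == 0L) NA_real_ else counts@tp / d
})

#' @rdname detectionMetrics
setMethod("accuracy", "ConfusionCounts", function(counts) {
  n <- counts@tp + counts@tn + counts@fp + counts@fn
  if (n == 0L) NA_real_ else 100 * (counts@tp + counts@tn) / n
})

#' Pool overlap counts over a whole case
#'
#' Treats a bone compartment as one 3D object: the ground-truth and predicted
#' pixel sets are pooled over every slice of the case before any ratio is
#' computed, yielding `|Sg|`, `|Sm|` and `|Sg n Sm|`.
#'
#' @param gt,pred aligned [MaskSequence-class] stacks (equal shape), or plain
#'   0/1 arrays.
#' @return an [OverlapCounts-class].
#' @export
poolOverlap <- function(gt, pred) {
  g <- if (is(gt, "MaskSequence")) sliceData(gt) else gt
  m <- if (is(pred, "MaskSequence")) sliceData(pred) else pred
  if (!identical(dim(g), dim(m)))
    stop("ground-truth and predicted stacks are misaligned")
  new("OverlapCounts", nG = as.numeric(sum(g > 0.5)),
      nM = as.numeric(sum(m > 0.5)),
      nInter = as.numeric(sum(g > 0.5 & m > 0.5)))
}

#' Case-level overlap metrics
#'
#' Computed from pooled [OverlapCounts-class]: Dice `2|Sg n Sm| / (|Sg| +
#' |Sm|)`, similarity (Jaccard) `|Sg n Sm| / |Sg u Sm|`, `TPR = |Sg n Sm| /
#' |Sg|`, `FPR = (|Sg u Sm| - |Sg|) / |Sg|` and `FNR = 1 - TPR`. Dice and
#' similarity of an empty/empty case are 1 (perfect-match convention); TPR,
#' FPR and FNR are `NA` when `|Sg| = 0`.
#'
#' Identity: `dice = 2 * SI / (1 + SI)`.
#'
#' @param x an [OverlapCounts-class], or a ground-truth mask (then `...` must
#'   carry the predicted mask, and the counts are pooled first).
#' @param ... optionally the predicted [MaskSequence-class]/array when `x` is
#'   a mask.
#' @return scalar metric value.
#' @name overlapMetrics
NULL

.asOverlap <- function(x, ...) {
  if (is(x, "OverlapCounts")) x else poolOverlap(x, ...)
}

#' @rdname overlapMetrics
setMethod("diceScore", "ANY", function(x, ...) {
  o <- .asOverlap(x, ...)
  if (o@nG + o@nM == 0) return(1)
  2 * o@nInter / (o@nG + o@nM)
})

#' @rdname overlapMetrics
setMethod("similarityIndex", "ANY", function(x, ...) {
  o <- .asOverlap(x, ...)
  u <- o@nG + o@nM - o@nInter
  if (u == 0) return(1)
  o@nInter / u
})

#' @rdname overlapMetrics
setMethod("truePositiveRate", "ANY", function(x, ...) {
  o <- .asOverlap(x, ...)
  if (o@nG == 0) return(NA_real_)
  o@nInter / o@nG
})

#' @rdname overlapMetrics
setMethod("falsePositiveRate", "ANY", function(x, ...) {
  o <- .asOverlap(x, ...)
  if (o@nG == 0) return(NA_real_)
  u <- o@nG + o@nM - o@nInter
  (u - o@nG) / o@nG
})

#' @rdname overlapMetrics
setMethod("falseNegativeRate", "ANY", function(x, ...) {
  tpr <- truePositiveRate(x, ...)
  1 - tpr
})

#' Bone volume of a mask stack
#'
#' Adds up all bone voxels across the slices of a case and multiplies by the
#' voxel size.
#'
#' @param mask a [MaskSequence-class] or 0/1 array.
#' @param spacing voxel size `(row_mm, col_mm, slice_mm)` in millimetres
#'   (default 1 mm^3 per voxel).
#' @return volume in cubic millimetres.
#' @export
boneVolume <- function(mask, spacing = c(1, 1, 1)) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  m <- if (is(mask, "MaskSequence")) sliceData(mask) else mask
  sum(m > 0.5) * prod(spacing)
}

#' Agreement between ground-truth and predicted volumes
#'
#' Ordinary least-squares regression of predicted on ground-truth volumes,
#' with the squared Pearson correlation. Used to check that automatic
#' segmentation estimates bone volume systematically (slope near 1, R^2 near
#' 1).
#'
#' @param gtVolumes,predVolumes equal-length numeric vectors (length >= 3).
#' @return list with `slope`, `intercept`, `rSquared` (all `NA` when the
#'   ground-truth volumes have zero variance).
#' @export
volumeAgreement <- function(gtVolumes, predVolumes) {
  if (length(gtVolumes) != length(predVolumes) || length(gtVolumes) < 3L)
    stop("need equal-length volume vectors of length >= 3")
  if (stats::var(gtVolumes) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, rSquared = NA_real_))
  fit <- stats::lm(predVolumes ~ gtVolumes)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rSquared = stats::cor(gtVolumes, predVolumes)^2)
}

#' Paired two-tailed t-test on per-case scores
#'
#' Compares two conditions evaluated on the same cases (e.g. automatic vs.
#' manual slice detection) with a paired two-tailed Student's t-test on the
#' per-case differences (`n - 1` degrees of freedom).
#'
#' @param a,b equal-length numeric vectors of per-case scores (length >= 2).
#' @return list with `t`, `p`, `df` and `degenerate` (TRUE when the
#'   differences have zero variance, in which case `t` and `p` are `NA`).
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("need equal-length score vectors of length >= 2")
  d <- a - b
  if (stats::var(d) == 0)
    return(list(t = NA_real_, p = NA_real_, df = length(a) - 1L,
                degenerate = TRUE))
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Round metrics the way the report tables print them
#'
#' Percentages to 2 decimals, ratios to 3 decimals. Raw values are kept
#' unrounded internally; this is display-only.
#'
#' @param x numeric value.
#' @param what `"percent"` or `"ratio"`.
#' @return rounded value.
#' @export
roundMetric <- function(x, what = c("percent", "ratio")) {
  round(x, if (match.arg(what) == "percent") 2L else 3L)
}

#' Build an evaluation report from per-case records
#'
#' @param perCase data.frame with one row per case x compartment and columns
#'   `caseId`, `compartment`, `dice`, `si`, `tpr`, `fpr`, `fnr`, `volumeGt`,
#'   `volumePred`, `degenerate`.
#' @return list with `perCase` and `aggregate` (unweighted means of the
#'   per-case scores, one row per compartment).
#' @export
evalReport <- function(perCase) {
  metrics <- c("dice", "si", "tpr", "fpr", "fnr")
  agg <- do.call(rbind, lapply(split(perCase, perCase$compartment),
                               function(d) {
    out <- data.frame(compartment = d$compartment[1])
    for (m in metrics) out[[m]] <- mean(d[[m]], na.rm = TRUE)
    out$nCases <- nrow(d)
    out
  }))
  rownames(agg) <- NULL
  list(perCase = perCase, aggregate = agg)
}

#' Write an evaluation report to disk
#'
#' The per-case table goes to `per_case.csv`, the aggregate means to
#' `summary.json`.
#'
#' @param report as returned by [evalReport()] / [evaluatePipeline()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeEvalReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$perCase, file.path(dir, "per_case.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$aggregate, file.path(dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
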