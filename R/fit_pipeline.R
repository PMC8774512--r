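#' @include pipeline.R
NULL

#' Assemble detection training data from cases
#'
#' Normalises each case, resizes every slice (and its ground-truth mask) to
#' the detection resolution and stacks them into `(H, W, 1, N)` tensors. The
#' detection network is trained on all slices — with and without bone — so it
#' learns to emit an all-black map on bone-free slices.
#'
#' @param cases list of cases (`sequence` + `masks`), e.g. from
#'   [generateDataset()].
#' @param compartment which ground-truth mask to use (default `"whole"`).
#' @param size detection resolution in pixels.
#' @return list with tensors `x` and `y`.
#' @export
casesToDetectionData <- function(cases, compartment = "whole", size = 128L) {
  xs <- list(); ys <- list()
  for (cs in cases) {
    img <- sliceData(normalizeIntensity(cs$sequence))
    msk <- sliceData(cs$masks[[compartment]])
    for (k in seq_len(dim(img)[3])) {
      xs[[length(xs) + 1L]] <- resizeGrid(img[, , k], size, "intensity")
      ys[[length(ys) + 1L]] <- resizeGrid(msk[, , k], size, "mask")
    }
  }
  n <- length(xs)
  list(x = array(unlist(xs), c(size, size, 1L, n)),
       y = array(unlist(ys), c(size, size, 1L, n)))
}

#' Assemble segmentation training data from cases
#'
#' Keeps only the slices in which the compartment appears (the segmentation
#' network is trained on bone slices only) at full resolution.
#'
#' @inheritParams casesToDetectionData
#' @return list with tensors `x` and `y`.
#' @export
casesToSegmentationData <- function(cases, compartment = "whole") {
  xs <- list(); ys <- list()
  for (cs in cases) {
    img <- sliceData(normalizeIntensity(cs$sequence))
    msk <- sliceData(cs$masks[[compartment]])
    for (k in which(.truthPresence(cs$masks[[compartment]]))) {
      xs[[length(xs) + 1L]] <- img[, , k]
      ys[[length(ys) + 1L]] <- msk[, , k]
    }
  }
  if (!length(xs)) stop("no bone slices found for this compartment")
  size <- dim(xs[[1]])
  n <- length(xs)
  list(x = array(unlist(xs), c(size[1], size[2], 1L, n)),
       y = array(unlist(ys), c(size[1], size[2], 1L, n)))
}

#' Train a two-stage detection + segmentation pipeline
#'
#' Trains, for one compartment, a detection U-net (binary cross-entropy on
#' resized slices, monitored by per-slice validation detection accuracy) and a
#' segmentation U-net (soft Dice on bone slices at full resolution, monitored
#' by validation Dice), then bundles both into a [BonePipeline-class].
#'
#' @param trainCases,valCases lists of cases (`sequence` + `masks`).
#' @param compartment compartment to train for (default `"whole"`).
#' @param baseWidth,depth architecture size (defaults 64 / 5; use a small
#'   `baseWidth` for desk-scale experiments).
#' @param detectionSize detection input resolution; segmentation runs at the
#'   cases' native slice size.
#' @param detectionConfig,segmentationConfig [TrainConfig-class] objects; the
#'   loss/monitor fields are forced to the stage-appropriate values.
#' @param seed weight-initialisation seed.
#' @param verbose print per-epoch progress.
#' @return list with `pipeline` ([BonePipeline-class]), `detectionHistory` and
#'   `segmentationHistory`.
#' @export
trainBonePipeline <- function(trainCases, valCases, compartment = "whole",
                              baseWidth = 64L, depth = 5L,
                              detectionSize = 128L,
                              detectionConfig = trainConfig(
                                loss = "binary_cross_entropy",
                                monitor = "val_accuracy"),
                              segmentationConfig = trainConfig(
                                loss = "soft_dice", monitor = "val_dice"),
                              seed = 1L, verbose = FALSE) {
  segSize <- dim(sliceData(trainCases[[1]]$sequence))[1]
  detTrain <- casesToDetectionData(trainCases, compartment, detectionSize)
  detVal <- casesToDetectionData(valCases, compartment, detectionSize)
  segTrain <- casesToSegmentationData(trainCases, compartment)
  segVal <- casesToSegmentationData(valCases, compartment)

  detModel <- buildUnet(unetSpec(baseWidth = baseWidth, depth = depth,
                                 inputSize = detectionSize), seed = seed)
  detectionConfig@loss <- "binary_cross_entropy"
  detectionConfig@monitor <- "val_accuracy"
  detFit <- trainModel(detModel, detTrain, detVal, detectionConfig,
                       verbose = verbose)

  segModel <- buildUnet(unetSpec(baseWidth = baseWidth, depth = depth,
                                 inputSize = segSize), seed = seed + 1L)
  segmentationConfig@loss <- "soft_dice"
  segmentationConfig@monitor <- "val_dice"
  segFit <- trainModel(segModel, segTrain, segVal, segmentationConfig,
                       verbose = verbose)

  segmenters <- stats::setNames(list(segFit$model), compartment)
  pipe <- bonePipeline(detectors = stats::setNames(list(detFit$model),
                                                   compartment),
                       segmenters = segmenters)
  list(pipeline = pipe, detectionHistory = detFit$history,
       segmentationHistory = segFit$history,
       detectionFit = detFit, segmentationFit = segFit)
}

#' Save / load a trained model with a plain-text sidecar
#'
#' The checkpoint is R-native serialisation; the sidecar records the
#' architecture spec and training seed in YAML for provenance.
#'
#' @param model a [UNetModel-class].
#' @param path checkpoint path (`.rds`); the sidecar is `<path>.yaml`.
#' @return invisibly, `path`.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "UNetModel"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  s <- model@spec
  yaml::write_yaml(list(inChannels = s@inChannels, outChannels = s@outChannels,
                        baseWidth = s@baseWidth, depth = s@depth,
                        inputSize = s@inputSize,
                        finalActivation = s@finalActivation,
                        seed = model@seed),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "UNetModel"))
  model
}
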