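# Shared phantom fixtures. The trained two-stage pipeline is expensive, so it
# is built once per test session and memoised; both the training-behaviour
# tests and the end-to-end evaluation reuse it.

.fixtures <- new.env(parent = emptyenv())

phantomStudySeed <- 20260101L

# Desk-scale study conditions: 30 cases split 20/5/5, 16 slices of 64x64,
# default generator noise/contrast, base width 8, detection at 32, Adam 1e-3,
# batch 16, <= 30 epochs with patience 6.
phantomStudyConfig <- function() {
  phantomConfig(nCases = 30L, nSlices = 16L, imageSize = 64L,
                seed = phantomStudySeed)
}

phantomStudy <- function() {
  if (!is.null(.fixtures$study)) return(.fixtures$study)
  cases <- generateDataset(phantomStudyConfig())
  ids <- vapply(cases, function(cs) caseId(cs$sequence), character(1))
  split <- splitCases(ids, c(0.70, 0.15, 0.15), seed = phantomStudySeed)
  pick <- function(v) cases[match(v, ids)]
  .fixtures$study <- list(cases = cases, split = split,
                          train = pick(split@trainIds),
                          val = pick(split@valIds),
                          test = pick(split@testIds))
  .fixtures$study
}

phantomStudyTrainConfig <- function(loss, monitor) {
  trainConfig(learningRate = 1e-3, batchSize = 16L, maxEpochs = 30L,
              patience = 6L, loss = loss, monitor = monitor,
              seed = phantomStudySeed)
}

trainedPhantomPipeline <- function() {
  if (!is.null(.fixtures$fit)) return(.fixtures$fit)
  st <- phantomStudy()
  .fixtures$fit <- trainBonePipeline(
    st$train, st$val, compartment = "whole", baseWidth = 8L, depth = 5L,
    detectionSize = 32L,
    detectionConfig = phantomStudyTrainConfig("binary_cross_entropy",
                                              "val_accuracy"),
    segmentationConfig = phantomStudyTrainConfig("soft_dice", "val_dice"),
    seed = phantomStudySeed)
  .fixtures$fit
}

# tiny noise-free phantoms for fast exact-recovery tests
noiseFreeCases <- function(n = 2L, nSlices = 12L, imageSize = 32L,
                           seed = 7L) {
  generateDataset(phantomConfig(nCases = n, nSlices = nSlices,
                                imageSize = imageSize, noiseSd = 0,
                                seed = seed))
}
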