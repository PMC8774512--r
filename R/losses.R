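#' @include unet.R
NULL

#' Soft Dice (negative Dice) loss
#'
#' Differentiable surrogate of the Dice overlap used to train the segmentation
#' network: `-(2 * sum(pred * target) + eps) / (sum(pred) + sum(target) +
#' eps)`. Values lie in `(-1, 0]`; a perfect overlap approaches -1. The
#' smoothing term `eps` makes the empty/empty case well-defined (and equal to
#' -1, the perfect-match convention).
#'
#' @param pred probability map (values in \[0, 1\]), any shape.
#' @param target binary mask of the same shape.
#' @param eps smoothing constant > 0 (default 1).
#' @return scalar loss.
#' @examples
#' m <- matrix(c(1, 0, 1, 0), 2)
#' softDiceLoss(m, m, eps = 1e-9)  # ~ -1
#' @export
softDiceLoss <- function(pred, target, eps = 1) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("pred and target must have identical shapes")
  if (eps <= 0) stop("eps must be > 0")
  num <- 2 * sum(pred * target) + eps
  den <- sum(pred) + sum(target) + eps
  -num / den
}

# Gradient of softDiceLoss w.r.t. pred (same shape as pred).
.softDiceGrad <- function(pred, target, eps = 1) {
  num <- 2 * sum(pred * target) + eps
  den <- sum(pred) + sum(target) + eps
  -(2 * target * den - num) / den^2
}

#' Binary cross-entropy loss
#'
#' Pixel-mean binary cross-entropy used to train the detection network.
#' Predictions are clipped to `[clip, 1 - clip]` before taking logs so the
#' loss stays finite.
#'
#' @param pred probability map.
#' @param target binary mask of the same shape.
#' @param clip clipping constant (default 1e-7).
#' @return scalar non-negative loss.
#' @export
binaryCrossEntropyLoss <- function(pred, target, clip = 1e-7) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("pred and target must have identical shapes")
  p <- pmin(pmax(pred, clip), 1 - clip)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

# Loss value and gradient w.r.t. the pre-sigmoid logits, for a batch.
.lossAndLogitGrad <- function(loss, prob, target, eps = 1) {
  if (loss == "soft_dice") {
    value <- softDiceLoss(prob, target, eps)
    dlogits <- .softDiceGrad(prob, target, eps) * prob * (1 - prob)
  } else {
    value <- binaryCrossEntropyLoss(prob, target)
    dlogits <- (prob - target) / length(prob)
  }
  dim(dlogits) <- dim(prob)
  list(value = value, dlogits = dlogits)
}
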