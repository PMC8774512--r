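#' @include losses.R
NULL

#' Configure the training schedule
#'
#' Defaults follow the reference schedule for the full-scale networks: Adam
#' with learning rate 1e-5, mini-batches of 16, an epoch cap of 300 and early
#' stopping after 35 epochs (midpoint of the 30-40 range) without improvement
#' of the monitored validation metric. Weights from the best-monitored epoch
#' are restored at stop.
#'
#' @param learningRate Adam step size (default 1e-5).
#' @param batchSize mini-batch size (default 16).
#' @param maxEpochs epoch cap (default 300).
#' @param patience early-stopping patience in epochs (default 35).
#' @param loss `"soft_dice"` (segmentation) or `"binary_cross_entropy"`
#'   (detection).
#' @param monitor `"val_dice"` or `"val_accuracy"` (per-slice detection
#'   accuracy); both are maximised.
#' @param seed shuffling seed.
#' @return a validated [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 1e-5, batchSize = 16L, maxEpochs = 300L,
                        patience = 35L,
                        loss = c("soft_dice", "binary_cross_entropy"),
                        monitor = c("val_dice", "val_accuracy"), seed = 1L) {
  new("TrainConfig", learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      patience = as.integer(patience), loss = match.arg(loss),
      monitor = match.arg(monitor), seed = as.integer(seed))
}

# Early-stopping state machine (maximising). update() returns TRUE while
# training should continue; stop exactly `patience` epochs after the last
# improvement.
.earlyStopping <- function(patience) {
  best <- -Inf
  bestEpoch <- 0L
  wait <- 0L
  list(
    update = function(value, epoch) {
      if (value > best) {
        best <<- value; bestEpoch <<- epoch; wait <<- 0L
      } else {
        wait <<- wait + 1L
      }
      wait < patience
    },
    best = function() best,
    bestEpoch = function() bestEpoch
  )
}

#' Trace the early-stopping rule over a scripted monitor sequence
#'
#' Applies the same maximise-with-patience rule the trainer uses to a given
#' sequence of per-epoch monitor values, without training anything. Useful to
#' verify the stopping contract: training halts exactly `patience` epochs
#' after the last improvement, and never beyond `maxEpochs`.
#'
#' @param values numeric vector of monitor values, one per epoch (epochs past
#'   `maxEpochs` are ignored).
#' @param patience epochs without improvement tolerated before stopping.
#' @param maxEpochs epoch cap.
#' @return list with `stoppedEpoch` and `bestEpoch`.
#' @export
simulateEarlyStopping <- function(values, patience, maxEpochs = 300L) {
  es <- .earlyStopping(patience)
  stopped <- min(length(values), maxEpochs)
  for (e in seq_len(min(length(values), maxEpochs))) {
    if (!es$update(values[e], e)) { stopped <- e; break }
  }
  list(stoppedEpoch = stopped, bestEpoch = es$bestEpoch())
}

# validation monitors -------------------------------------------------------

.monitorDice <- function(model, val, probThreshold = 0.5) {
  prob <- predictProb(model, val$x)
  pred <- prob >= probThreshold
  truth <- val$y > 0.5
  inter <- sum(pred & truth)
  tot <- sum(pred) + sum(truth)
  if (tot == 0) 1 else 2 * inter / tot
}

.monitorDetectionAccuracy <- function(model, val, probThreshold = 0.5,
                                      minArea = 1L) {
  prob <- predictProb(model, val$x)
  n <- dim(prob)[4]
  predPos <- vapply(seq_len(n), function(i)
    sum(prob[, , , i] >= probThreshold) >= minArea, logical(1))
  truthPos <- vapply(seq_len(n), function(i) any(val$y[, , , i] > 0.5),
                     logical(1))
  mean(predPos == truthPos)
}

#' Train a U-net model
#'
#' Mini-batch Adam training with early stopping. Per epoch, the training pairs
#' are shuffled (deterministically given `config@seed`), the configured loss
#' is backpropagated, and the monitored validation metric is evaluated;
#' training stops at `maxEpochs` or once the monitor has not improved for
#' `patience` consecutive epochs, restoring the best-epoch weights.
#'
#' Adam uses beta1 = 0.9, beta2 = 0.999, eps = 1e-8. A non-finite training
#' loss aborts with a diagnostic.
#'
#' @param model a [UNetModel-class].
#' @param train,val lists with elements `x` (images, `(H, W, 1, N)`) and `y`
#'   (masks, same shape); both non-empty.
#' @param config a [TrainConfig-class].
#' @param monitorFn optional override of the validation monitor: a
#'   `function(model, val, epoch)` returning a scalar to maximise (used to
#'   script stopping behaviour in tests).
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-epoch weights) and `history` (data.frame
#'   with `epoch`, `loss`, `monitor`), plus `stoppedEpoch` and `bestEpoch`.
#' @export
trainModel <- function(model, train, val, config, monitorFn = NULL,
                       verbose = FALSE) {
  stopifnot(is(model, "UNetModel"), is(config, "TrainConfig"))
  validObject(config)
  for (nm in c("train", "val")) {
    d <- get(nm)
    if (is.null(d$x) || is.null(d$y) || length(dim(d$x)) != 4L ||
        dim(d$x)[4] < 1L)
      stop(sprintf("%s set must be a non-empty list(x, y) of 4-d arrays", nm))
    if (!identical(dim(d$x), dim(d$y)))
      stop(sprintf("%s images and masks must have identical shapes", nm))
  }
  p <- model@params
  mState <- lapply(p, function(w) array(0, dim(w) %||% length(w)))
  vState <- mState
  beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8
  lr <- config@learningRate
  nTrain <- dim(train$x)[4]
  es <- .earlyStopping(config@patience)
  bestParams <- p
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        monitor = numeric(0))
  if (is.null(monitorFn)) {
    monitorFn <- if (config@monitor == "val_dice") {
      function(model, val, epoch) .monitorDice(model, val)
    } else {
      function(model, val, epoch) .monitorDetectionAccuracy(model, val)
    }
  }
  t <- 0L
  stoppedEpoch <- config@maxEpochs
  .withSeed(config@seed, function() {
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample.int(nTrain)
      epochLoss <- 0
      nBatches <- 0L
      for (i in seq(1L, nTrain, by = config@batchSize)) {
        sel <- ord[i:min(nTrain, i + config@batchSize - 1L)]
        xb <- train$x[, , , sel, drop = FALSE]
        yb <- train$y[, , , sel, drop = FALSE]
        fwd <- .unetForward(model, xb, wantCache = TRUE)
        lg <- .lossAndLogitGrad(config@loss, fwd$prob, yb)
        if (!is.finite(lg$value))
          stop(sprintf("non-finite training loss at epoch %d (loss=%g)",
                       epoch, lg$value))
        grads <- .unetBackward(model, fwd$cache, lg$dlogits)
        t <<- t + 1L
        for (nm in names(p)) {
          mState[[nm]] <<- beta1 * mState[[nm]] + (1 - beta1) * grads[[nm]]
          vState[[nm]] <<- beta2 * vState[[nm]] + (1 - beta2) * grads[[nm]]^2
          mhat <- mState[[nm]] / (1 - beta1^t)
          vhat <- vState[[nm]] / (1 - beta2^t)
          p[[nm]] <<- p[[nm]] - lr * mhat / (sqrt(vhat) + adamEps)
        }
        model@params <- p
        epochLoss <- epochLoss + lg$value
        nBatches <- nBatches + 1L
      }
      monValue <- monitorFn(model, val, epoch)
      history[nrow(history) + 1L, ] <<- list(epoch, epochLoss / nBatches,
                                             monValue)
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  monitor %.5f", epoch,
                        epochLoss / nBatches, monValue))
      improved <- monValue > es$best()
      keepGoing <- es$update(monValue, epoch)
      if (improved) bestParams <<- p
      if (!keepGoing) { stoppedEpoch <<- epoch; break }
    }
  })
  model@params <- bestParams
  list(model = model, history = history, stoppedEpoch = stoppedEpoch,
       bestEpoch = es$bestEpoch())
}
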