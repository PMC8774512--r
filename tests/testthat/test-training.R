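test_that("early stopping halts exactly `patience` epochs after the last improvement", {
  # improvements at epochs 1 and 2, then a plateau
  values <- c(0.5, 0.6, rep(0.6, 100))
  for (patience in c(3L, 10L, 35L)) {
    res <- simulateEarlyStopping(values, patience, maxEpochs = 300L)
    expect_identical(res$stoppedEpoch, 2L + patience)
    expect_identical(res$bestEpoch, 2L)
  }
  # a late improvement resets the counter
  v2 <- c(0.5, 0.4, 0.4, 0.7, rep(0.7, 50))
  res2 <- simulateEarlyStopping(v2, 5L, maxEpochs = 300L)
  expect_identical(res2$stoppedEpoch, 4L + 5L)
  expect_identical(res2$bestEpoch, 4L)
  # monotone improvement never stops before the epoch cap
  res3 <- simulateEarlyStopping(seq(0, 1, length.out = 400), 5L,
                                maxEpochs = 300L)
  expect_identical(res3$stoppedEpoch, 300L)
})

tinyData <- function(n = 6L, size = 16L, seed = 1L) {
  set.seed(seed)
  x <- array(runif(size * size * n), c(size, size, 1L, n))
  y <- array(0, dim(x))
  y[4:9, 4:9, , ] <- 1
  x[y == 1] <- x[y == 1] + 1
  list(x = x / 2, y = y)
}

test_that("the trainer honours the stubbed monitor and the epoch cap", {
  data <- tinyData()
  model <- buildUnet(unetSpec(baseWidth = 2L, depth = 3L, inputSize = 16L))
  cfg <- trainConfig(learningRate = 1e-3, batchSize = 4L, maxEpochs = 30L,
                     patience = 4L, loss = "soft_dice", monitor = "val_dice")
  script <- c(0.5, 0.6, rep(0.6, 50))
  fit <- trainModel(model, data, data, cfg,
                    monitorFn = function(model, val, epoch) script[epoch])
  expect_identical(fit$stoppedEpoch, 6L)  # last improvement at 2 + patience 4
  expect_identical(fit$bestEpoch, 2L)
  expect_identical(nrow(fit$history), 6L)
  # maxEpochs = 1 trains exactly one epoch regardless of patience
  cfg1 <- trainConfig(learningRate = 1e-3, batchSize = 4L, maxEpochs = 1L,
                      patience = 0L, loss = "soft_dice", monitor = "val_dice")
  fit1 <- trainModel(model, data, data, cfg1,
                     monitorFn = function(model, val, epoch) 0.5)
  expect_identical(fit1$stoppedEpoch, 1L)
  expect_identical(nrow(fit1$history), 1L)
  # the patience < maxEpochs invariant is enforced at construction
  expect_error(trainConfig(patience = 400L, maxEpochs = 300L), "patience")
})

test_that("training is deterministic given the seed", {
  data <- tinyData()
  spec <- unetSpec(baseWidth = 2L, depth = 3L, inputSize = 16L)
  cfg <- trainConfig(learningRate = 1e-3, batchSize = 4L, maxEpochs = 3L,
                     patience = 2L, loss = "soft_dice", monitor = "val_dice",
                     seed = 11L)
  f1 <- trainModel(buildUnet(spec, seed = 2L), data, data, cfg)
  f2 <- trainModel(buildUnet(spec, seed = 2L), data, data, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@params, f2$model@params)
})

test_that("degenerate training inputs are rejected", {
  model <- buildUnet(unetSpec(baseWidth = 2L, depth = 3L, inputSize = 16L))
  cfg <- trainConfig(learningRate = 1e-3, batchSize = 4L, maxEpochs = 2L,
                     patience = 1L)
  expect_error(trainModel(model, list(x = NULL, y = NULL), tinyData(), cfg),
               "non-empty")
  bad <- tinyData()
  bad$y <- bad$y[, , , 1:3, drop = FALSE]
  expect_error(trainModel(model, bad, tinyData(), cfg), "identical shapes")
})

test_that("soft-dice training on noise-free phantoms reaches -0.90 within 50 epochs", {
  cases <- generateDataset(phantomConfig(nCases = 10L, nSlices = 10L,
                                         imageSize = 64L, noiseSd = 0,
                                         seed = 77L))
  train <- casesToSegmentationData(cases[1:8])
  val <- casesToSegmentationData(cases[9:10])
  model <- buildUnet(unetSpec(baseWidth = 8L, depth = 5L, inputSize = 64L),
                     seed = 77L)
  cfg <- trainConfig(learningRate = 1e-3, batchSize = 16L, maxEpochs = 50L,
                     patience = 8L, loss = "soft_dice", monitor = "val_dice",
                     seed = 77L)
  fit <- trainModel(model, train, val, cfg)
  # best-so-far training loss decreases monotonically and crosses -0.90
  best <- cummin(fit$history$loss)
  expect_true(all(diff(best) <= 0))
  expect_lte(min(fit$history$loss), -0.90)
  expect_lte(fit$stoppedEpoch, 50L)
})
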