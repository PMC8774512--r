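test_that("presence confusion counts match elementwise enumeration", {
  set.seed(30)
  # identical vectors: no errors
  v <- runif(20) > 0.5
  c0 <- confusionFromPresence(v, v)
  expect_identical(c0@fp + c0@fn, 0L)
  # all-false truth, all-true prediction
  cAll <- confusionFromPresence(rep(TRUE, 7), rep(FALSE, 7))
  expect_identical(cAll@fp, 7L)
  # random vectors against a brute-force per-element tally
  for (rep in 1:10) {
    pred <- runif(50) > 0.5
    truth <- runif(50) > 0.5
    cc <- confusionFromPresence(pred, truth)
    tally <- table(factor(paste0(pred, truth),
                          levels = c("TRUETRUE", "FALSEFALSE",
                                     "TRUEFALSE", "FALSETRUE")))
    expect_identical(c(cc@tp, cc@tn, cc@fp, cc@fn), unname(as.integer(tally)))
    expect_identical(cc@tp + cc@tn + cc@fp + cc@fn, 50L)
  }
  expect_error(confusionFromPresence(c(TRUE), c(TRUE, FALSE)), "equal lengths")
})

test_that("detection metrics reproduce the reference confusion-table rows", {
  # rows as (fp, fn, tp, tn) with the published 3-decimal / 2-decimal cells
  rows <- list(
    tibia = list(c = c(20L, 9L, 1679L, 692L),
                 recall = 0.995, precision = 0.988, accuracy = 98.79),
    femur = list(c = c(20L, 8L, 1786L, 586L),
                 recall = 0.996, precision = 0.989, accuracy = 98.83),
    patella = list(c = c(9L, 28L, 950L, 1413L),
                   recall = 0.971, precision = 0.991, accuracy = 98.46),
    whole = list(c = c(20L, 9L, 1831L, 540L),
                 recall = 0.995, precision = 0.989, accuracy = 98.79))
  for (nm in names(rows)) {
    r <- rows[[nm]]
    cc <- new("ConfusionCounts", fp = r$c[1], fn = r$c[2], tp = r$c[3],
              tn = r$c[4])
    expect_identical(roundMetric(recall(cc), "ratio"), r$recall, label = nm)
    expect_identical(roundMetric(precision(cc), "ratio"), r$precision,
                     label = nm)
    expect_identical(roundMetric(accuracy(cc), "percent"), r$accuracy,
                     label = nm)
  }
  # undefined-metric sentinels instead of errors
  expect_true(is.na(recall(new("ConfusionCounts", tp = 0L, fn = 0L, fp = 2L,
                               tn = 3L))))
  expect_true(is.na(precision(new("ConfusionCounts", tp = 0L, fn = 1L,
                                  fp = 0L, tn = 3L))))
})

test_that("pooled overlap counts equal brute-force voxel-set operations", {
  set.seed(31)
  for (rep in 1:20) {
    gt <- randomMask(c(8, 8, 5), runif(1, 0.1, 0.9))
    pred <- randomMask(c(8, 8, 5), runif(1, 0.1, 0.9))
    o <- poolOverlap(gt, pred)
    oo <- oracleOverlap(gt, pred)
    expect_identical(c(o@nG, o@nM, o@nInter),
                     as.numeric(c(oo$nG, oo$nM, oo$nInter)))
  }
  # identical stacks and disjoint stacks
  m <- randomMask(c(8, 8, 3), 0.4)
  oi <- poolOverlap(m, m)
  expect_equal(c(oi@nG, oi@nM, oi@nInter), rep(sum(m), 3))
  od <- poolOverlap(m, 1 - m)
  expect_identical(od@nInter, 0)
  expect_error(poolOverlap(randomMask(c(4, 4, 2), 0.5),
                           randomMask(c(4, 4, 3), 0.5)), "misaligned")
})

test_that("overlap ratios follow their formulas and identities", {
  o <- new("OverlapCounts", nG = 10, nM = 10, nInter = 5)
  expect_equal(diceScore(o), 0.5)
  expect_equal(similarityIndex(o), 1 / 3)
  expect_equal(truePositiveRate(o), 0.5)
  expect_equal(falsePositiveRate(o), 0.5)
  expect_equal(falseNegativeRate(o), 0.5)
  # identical non-empty masks
  oid <- new("OverlapCounts", nG = 7, nM = 7, nInter = 7)
  expect_equal(c(diceScore(oid), similarityIndex(oid), truePositiveRate(oid)),
               c(1, 1, 1))
  expect_equal(c(falsePositiveRate(oid), falseNegativeRate(oid)), c(0, 0))
  # FNR = 1 - TPR: a TPR of 98.51% forces an FNR of 1.49%
  o3 <- new("OverlapCounts", nG = 10000, nM = 10000, nInter = 9851)
  expect_equal(100 * truePositiveRate(o3), 98.51)
  expect_equal(100 * falseNegativeRate(o3), 1.49)
  # empty/empty convention
  oe <- new("OverlapCounts", nG = 0, nM = 0, nInter = 0)
  expect_identical(diceScore(oe), 1)
  expect_identical(similarityIndex(oe), 1)
  expect_true(is.na(truePositiveRate(oe)))
})

test_that("dice = 2 SI / (1 + SI) and metrics match oracles on random stacks", {
  set.seed(32)
  for (rep in 1:200) {
    gt <- randomMask(c(8, 8, 5), runif(1, 0.05, 0.95))
    pred <- randomMask(c(8, 8, 5), runif(1, 0.05, 0.95))
    o <- poolOverlap(gt, pred)
    d <- diceScore(o); s <- similarityIndex(o)
    expect_equal(d, 2 * s / (1 + s), tolerance = 1e-13)
    expect_equal(d, oracleDice(gt, pred), tolerance = 1e-13)
    expect_equal(s, oracleSI(gt, pred), tolerance = 1e-13)
    if (o@nG > 0) {
      expect_equal(falseNegativeRate(o) + truePositiveRate(o), 1)
      expect_gte(falsePositiveRate(o), 0)
    }
    expect_true(d >= 0 && d <= 1 && s >= 0 && s <= 1)
  }
})

test_that("bone volume is voxel count times voxel size", {
  m <- array(0, c(10, 10, 4))
  m[sample(length(m), 100)] <- 1
  expect_equal(boneVolume(m, c(1, 1, 0.5)), 50)
  expect_equal(boneVolume(array(0, c(5, 5, 2))), 0)
  set.seed(33)
  for (rep in 1:10) {
    m <- randomMask(c(6, 6, 3), runif(1))
    sp <- runif(3, 0.1, 2)
    expect_equal(boneVolume(m, sp), sum(m) * prod(sp))
  }
  expect_error(boneVolume(m, c(1, -1, 1)), "positive")
})

test_that("volume agreement matches closed-form least squares", {
  gt <- c(10, 20, 30, 40, 50)
  expect_equal(volumeAgreement(gt, gt),
               list(slope = 1, intercept = 0, rSquared = 1))
  dbl <- volumeAgreement(gt, 2 * gt)
  expect_equal(dbl$slope, 2)
  expect_equal(dbl$rSquared, 1)
  set.seed(34)
  x <- runif(20, 0, 100)
  y <- 0.98 * x + rnorm(20, 0, 3)
  got <- volumeAgreement(x, y)
  # closed-form OLS evaluated directly
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(got$slope, slope, tolerance = 1e-12)
  expect_equal(got$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_equal(got$rSquared, cor(x, y)^2, tolerance = 1e-12)
  expect_true(is.na(volumeAgreement(rep(1, 5), rnorm(5))$slope))
})

test_that("the paired comparison matches the textbook t statistic", {
  # equal vectors have zero-variance differences: degenerate sentinel
  a <- c(0.9, 0.8, 0.95)
  expect_true(pairedTTest(a, a)$degenerate)
  # constant shift with small noise is significant for n = 15
  set.seed(35)
  b <- rnorm(15, 0.9, 0.01)
  shifted <- b + 0.05 + rnorm(15, 0, 0.002)
  expect_lt(pairedTTest(shifted, b)$p, 0.05)
  # fixed length-6 vectors against the hand formula
  x <- c(0.91, 0.88, 0.95, 0.90, 0.86, 0.93)
  y <- c(0.89, 0.90, 0.91, 0.88, 0.87, 0.90)
  d <- x - y
  tHand <- mean(d) / (sd(d) / sqrt(6))
  pHand <- 2 * pt(-abs(tHand), df = 5)
  got <- pairedTTest(x, y)
  expect_equal(got$t, tHand, tolerance = 1e-12)
  expect_equal(got$p, pHand, tolerance = 1e-12)
  expect_identical(got$df, 5)
})

test_that("report aggregation is the unweighted mean of per-case scores", {
  perCase <- data.frame(
    caseId = c("a", "b", "c", "a", "b"),
    compartment = c("femur", "femur", "femur", "tibia", "tibia"),
    dice = c(0.9, 0.8, 1.0, 0.7, 0.9), si = c(0.8, 0.7, 1.0, 0.6, 0.8),
    tpr = c(1, 1, 1, 1, 1), fpr = c(0, 0, 0, 0, 0), fnr = c(0, 0, 0, 0, 0),
    volumeGt = 1:5, volumePred = 1:5, degenerate = FALSE)
  rep <- evalReport(perCase)
  femur <- rep$aggregate[rep$aggregate$compartment == "femur", ]
  expect_equal(femur$dice, mean(c(0.9, 0.8, 1.0)))
  expect_equal(femur$si, mean(c(0.8, 0.7, 1.0)))
  expect_identical(femur$nCases, 3L)
  dir <- withr::local_tempdir()
  writeEvalReport(rep, dir)
  expect_true(file.exists(file.path(dir, "per_case.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  back <- read.csv(file.path(dir, "per_case.csv"))
  expect_equal(back$dice, perCase$dice)
})
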