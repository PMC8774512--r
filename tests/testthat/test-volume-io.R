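test_that("crop arithmetic matches the preprocessing contract", {
  g <- matrix(rnorm(384 * 384), 384)
  out <- cropBorders(g, 16)
  expect_identical(dim(out), c(352L, 352L))
  expect_identical(out, g[17:368, 17:368])
  expect_identical(cropBorders(g, 0), g)
  expect_error(cropBorders(matrix(0, 10, 10), 5), "too large")
})

test_that("successive crops compose additively", {
  set.seed(1)
  for (rep in 1:5) {
    h <- sample(40:80, 1); w <- sample(40:80, 1)
    g <- matrix(rnorm(h * w), h)
    a <- sample(1:5, 1); b <- sample(1:5, 1)
    expect_identical(cropBorders(cropBorders(g, a), b), cropBorders(g, a + b))
  }
})

test_that("resize keeps masks binary and constants constant", {
  set.seed(2)
  m <- (matrix(runif(352 * 352), 352) > 0.8) + 0
  small <- resizeGrid(m, 128, "mask")
  expect_identical(dim(small), c(128L, 128L))
  expect_true(all(small %in% c(0, 1)))
  # same-size mask resize is the identity
  expect_identical(resizeGrid(m, 352, "mask"), m)
  # interpolation of a constant field is that constant
  ones <- matrix(1, 64, 64)
  expect_equal(resizeGrid(ones, 48, "intensity"), matrix(1, 48, 48))
  expect_identical(resizeGrid(ones, 48, "mask"), matrix(1, 48, 48))
})

test_that("intensity normalisation is per case with the degenerate rule", {
  x <- array(seq(0, 4095, length.out = 4 * 4 * 2), c(4, 4, 2))
  seq1 <- normalizeIntensity(MRISequence("a", x))
  expect_equal(range(sliceData(seq1)), c(0, 1))
  expect_equal(max(sliceData(seq1)), 1)
  # constant case maps to zeros
  seq2 <- normalizeIntensity(MRISequence("b", array(7, c(4, 4, 2))))
  expect_true(all(sliceData(seq2) == 0))
  # idempotent on an already-normalised case
  expect_equal(sliceData(normalizeIntensity(seq1)), sliceData(seq1))
})

test_that("case split reproduces the 99 -> 69/15/15 partition and slice totals", {
  ids <- sprintf("case%02d", 1:99)
  sp <- splitCases(ids, c(0.70, 0.15, 0.15), seed = 1L)
  expect_length(sp@trainIds, 69L)
  expect_length(sp@valIds, 15L)
  expect_length(sp@testIds, 15L)
  expect_identical(length(sp@trainIds) * 160L, 11040L)
  expect_identical(length(sp@valIds) * 160L, 2400L)
  # rounding rule: 10 ids at the same fractions force 6/2/2
  sp10 <- splitCases(sprintf("c%d", 1:10), c(0.70, 0.15, 0.15), seed = 1L)
  expect_identical(vapply(list(sp10@trainIds, sp10@valIds, sp10@testIds),
                          length, integer(1)), c(6L, 2L, 2L))
  expect_error(splitCases(c("a", "b"), c(0.70, 0.15, 0.15)), "at least 3")
  expect_error(splitCases(ids, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("case split partitions the input for random seeds", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    ids <- paste0("id", sample.int(1e6, n))
    sp <- splitCases(ids, c(0.70, 0.15, 0.15), seed = sample.int(1e6, 1))
    all3 <- c(sp@trainIds, sp@valIds, sp@testIds)
    expect_identical(sort(all3), sort(ids))  # exhaustive
    expect_identical(anyDuplicated(all3), 0L)  # disjoint
    expect_identical(splitCases(ids, seed = 5L), splitCases(ids, seed = 5L))
  }
})

test_that("mask and intensity stacks round-trip through the supported formats", {
  dir <- withr::local_tempdir()
  set.seed(4)
  m <- MaskSequence("c1", "femur", randomMask(c(16, 16, 5), 0.3))
  for (fmt in c("png_stack", "nifti", "rds")) {
    path <- file.path(dir, paste0("m_", fmt),
                      if (fmt == "nifti") "mask.nii" else "")
    path <- sub("/$", "", path)
    writeMasks(m, path, fmt)
    back <- readMasks(path, fmt, compartment = "femur")
    expect_identical(sliceData(back), sliceData(m), label = fmt)
  }
  # rds intensities are bit-exact
  x <- MRISequence("c2", array(runif(16 * 16 * 4), c(16, 16, 4)),
                   spacing = c(0.5, 0.5, 2))
  writeSequence(x, file.path(dir, "seq.rds"), "rds")
  back <- readSequence(file.path(dir, "seq.rds"), "rds")
  expect_identical(sliceData(back), sliceData(x))
  expect_identical(spacing(back), c(0.5, 0.5, 2))
  # nifti keeps values and spacing
  writeSequence(x, file.path(dir, "seq.nii"), "nifti")
  backN <- readSequence(file.path(dir, "seq.nii"), "nifti")
  expect_equal(sliceData(backN), sliceData(x))
  expect_equal(spacing(backN), c(0.5, 0.5, 2))
})

test_that("png stacks are ordered numerically and shape mismatches are named", {
  dir <- withr::local_tempdir()
  # write slices out of lexical order: slice_2 < slice_10 numerically
  png::writePNG(matrix(0, 8, 8), file.path(dir, "slice_2.png"))
  png::writePNG(matrix(1, 8, 8), file.path(dir, "slice_10.png"))
  seq <- readSequence(dir, "png_stack")
  expect_equal(sliceData(seq)[1, 1, ], c(0, 1))
  png::writePNG(matrix(0, 6, 6), file.path(dir, "slice_11.png"))
  expect_error(readSequence(dir, "png_stack"), "slice_11")
})

test_that("unsupported format tokens fail with guidance", {
  expect_error(readSequence("x", "npz"), "not supported")
  expect_error(readSequence("x", "dicom_dir"), "NIfTI")
  expect_error(writeSequence(MRISequence("a", array(0, c(4, 4, 1))),
                             "x", "npz"), "not supported")
  expect_error(readSequence("x", "bogus"))
})
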