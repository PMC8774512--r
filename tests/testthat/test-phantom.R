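test_that("compartment masks are non-empty exactly on the drawn slice interval", {
  # fixed interval: femur restricted to start 22, end 134 in a 160-slice stack
  comps <- kneeseg:::.defaultCompartments(160L)
  comps$femur$startRange <- c(22L, 22L)
  comps$femur$endRange <- c(134L, 134L)
  cfg <- phantomConfig(nCases = 1L, nSlices = 160L, imageSize = 48L,
                       compartments = comps, noiseSd = 0, seed = 3L)
  cs <- generateCase(cfg, 1L)
  pres <- apply(sliceData(cs$masks$femur), 3, function(m) any(m > 0))
  expect_identical(which(pres), 22:134)
  expect_identical(cs$info$femur$start, 22L)
  expect_identical(cs$info$femur$end, 134L)

  # general property over several cases: presence == indicator of [start, end]
  cfg2 <- phantomConfig(nCases = 4L, nSlices = 24L, imageSize = 32L, seed = 11L)
  for (i in seq_len(4L)) {
    cs <- generateCase(cfg2, i)
    for (nm in c("femur", "tibia", "patella")) {
      pres <- apply(sliceData(cs$masks[[nm]]), 3, function(m) any(m > 0))
      expect_identical(which(pres),
                       seq(cs$info[[nm]]$start, cs$info[[nm]]$end))
    }
  }
})

test_that("masks are binary, pairwise disjoint, and whole = union", {
  cfg <- phantomConfig(nCases = 3L, nSlices = 20L, imageSize = 40L, seed = 5L)
  for (i in 1:3) {
    cs <- generateCase(cfg, i)
    overlap <- sliceData(cs$masks$femur) + sliceData(cs$masks$tibia) +
      sliceData(cs$masks$patella)
    expect_true(all(overlap %in% c(0, 1)))
    for (m in cs$masks) expect_true(all(sliceData(m) %in% c(0, 1)))
    expect_identical(sliceData(cs$masks$whole), pmin(overlap, 1))
    expect_identical(nSlices(cs$masks$whole), 20L)
  }
})

test_that("noise-free background pixels equal the background intensity exactly", {
  cfg <- phantomConfig(nCases = 1L, nSlices = 12L, imageSize = 32L,
                       noiseSd = 0, backgroundIntensity = 0.15,
                       boneIntensity = 0.85, seed = 2L)
  cs <- generateCase(cfg, 1L)
  img <- sliceData(cs$sequence)
  bone <- sliceData(cs$masks$whole) > 0
  expect_true(all(img[!bone] == 0.15))
  expect_true(all(img[bone] == 0.85))
})

test_that("generation is bit-identical given (seed, caseIndex)", {
  cfg <- phantomConfig(nCases = 2L, nSlices = 10L, imageSize = 32L, seed = 9L)
  a <- generateCase(cfg, 2L)
  b <- generateCase(cfg, 2L)
  expect_identical(sliceData(a$sequence), sliceData(b$sequence))
  expect_identical(lapply(a$masks, sliceData), lapply(b$masks, sliceData))
  # distinct cases draw distinct geometry
  c1 <- generateCase(cfg, 1L)
  expect_false(identical(sliceData(c1$sequence), sliceData(a$sequence)))
})

test_that("a midpoint-threshold segmenter recovers the mask exactly when noise-free", {
  cs <- noiseFreeCases(n = 1L)[[1]]
  img <- sliceData(cs$sequence)
  recovered <- (img > 0.5) + 0
  expect_identical(recovered, sliceData(cs$masks$whole))
})

test_that("invalid configurations are rejected", {
  expect_error(phantomConfig(nCases = 1L, nSlices = 10L, imageSize = 32L,
                             noiseSd = 0.3),
               "3 \\* noiseSd")
  # explicit override allows low contrast
  expect_s4_class(phantomConfig(nCases = 1L, nSlices = 10L, imageSize = 32L,
                                noiseSd = 0.3, enforceSeparability = FALSE),
                  "PhantomConfig")
  comps <- kneeseg:::.defaultCompartments(10L)
  comps$femur$startRange <- c(8L, 9L)
  comps$femur$endRange <- c(5L, 9L)   # start range not before end range
  expect_error(phantomConfig(nCases = 1L, nSlices = 10L, imageSize = 32L,
                             compartments = comps),
               "start range")
  expect_error(generateCase(phantomConfig(2L, 10L, 32L), 3L), "caseIndex")
})

test_that("generateDataset writes cases and a readable manifest", {
  dir <- withr::local_tempdir()
  cfg <- phantomConfig(nCases = 3L, nSlices = 8L, imageSize = 32L, seed = 4L)
  cases <- generateDataset(cfg, dir = dir, format = "rds")
  expect_length(cases, 3L)
  man <- readManifest(file.path(dir, "manifest.txt"))
  expect_identical(nrow(man), 3L)
  expect_identical(man$nSlices, rep(8L, 3L))
  expect_identical(man$femurStart[1], cases[[1]]$info$femur$start)
  # total slice count over the dataset
  expect_identical(sum(man$nSlices), 24L)
  rt <- readSequence(file.path(dir, "phantom_002", "image"), "rds")
  expect_identical(sliceData(rt), sliceData(cases[[2]]$sequence))
})
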