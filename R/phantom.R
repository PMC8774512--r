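#' @include accessors.R
NULL

# Default per-compartment geometry, expressed as fractions of image size and
# of the canonical 160-slice stack. Slice anchors: femur appears around slices
# 22-134, tibia 30-136, patella 50-115 (1-based, inclusive). Centre regions
# are fixed and non-overlapping so compartment masks are disjoint by
# construction: femur occupies the upper half, tibia the lower half, patella
# an anterior (left) strip.
.defaultCompartments <- function(nSlices) {
  scale <- function(k) max(1L, min(nSlices, as.integer(round(k / 160 * nSlices))))
  win <- function(lo, hi) c(scale(lo), scale(hi))
  list(
    femur = list(startRange = win(18, 26), endRange = win(130, 138),
                 cx = c(0.48, 0.60), cy = c(0.22, 0.30),
                 rx = c(0.10, 0.17), ry = c(0.08, 0.14), drift = 0.02),
    tibia = list(startRange = win(26, 34), endRange = win(132, 140),
                 cx = c(0.48, 0.60), cy = c(0.70, 0.78),
                 rx = c(0.10, 0.17), ry = c(0.08, 0.14), drift = 0.02),
    patella = list(startRange = win(46, 54), endRange = win(111, 119),
                   cx = c(0.10, 0.18), cy = c(0.42, 0.58),
                   rx = c(0.04, 0.08), ry = c(0.06, 0.12), drift = 0.02)
  )
}

# Extreme extents of a compartment's centre region; used to prove disjointness.
.compartmentExtent <- function(cp) {
  list(xlo = min(cp$cx) - max(cp$rx) - cp$drift,
       xhi = max(cp$cx) + max(cp$rx) + cp$drift,
       ylo = min(cp$cy) - max(cp$ry) - cp$drift,
       yhi = max(cp$cy) + max(cp$ry) + cp$drift)
}

.checkDisjointRegions <- function(compartments) {
  ex <- lapply(compartments, .compartmentExtent)
  nm <- names(compartments)
  for (i in seq_along(ex)) {
    for (j in seq_len(i - 1L)) {
      a <- ex[[i]]; b <- ex[[j]]
      sepX <- a$xhi <= b$xlo || b$xhi <= a$xlo
      sepY <- a$yhi <= b$ylo || b$yhi <= a$ylo
      if (!sepX && !sepY)
        stop(sprintf("compartment regions '%s' and '%s' may overlap; %s",
                     nm[i], nm[j],
                     "adjust centre/radius ranges so they are separated"))
    }
  }
  invisible(TRUE)
}

#' Configure the synthetic knee phantom generator
#'
#' Builds a [PhantomConfig-class] describing a family of synthetic knee-like
#' MRI cases: each case is a stack of `nSlices` square slices in which each
#' bone compartment appears on a contiguous slice interval (drawn per case
#' from `startRange`/`endRange`) as a filled ellipse whose centre drifts
#' smoothly and whose radii taper towards the interval ends, mimicking bone
#' appearance and disappearance. Compartment centre regions are fixed and
#' non-overlapping (femur upper half, tibia lower half, patella anterior
#' strip) so the masks are pairwise disjoint and the whole-knee mask is their
#' union. Intensities are `backgroundIntensity` outside bone and
#' `boneIntensity` inside, plus additive Gaussian noise clipped to \[0, 1\].
#'
#' The default slice windows scale the canonical 160-slice anchors (femur
#' ~22-134, tibia ~30-136, patella ~50-115) to `nSlices`.
#'
#' @param nCases number of cases.
#' @param nSlices slices per case (default 160).
#' @param imageSize square slice size in pixels (default 384).
#' @param compartments named list of compartment geometries; see
#'   [PhantomConfig-class]. Defaults to `nSlices`-scaled knee anchors.
#' @param noiseSd additive Gaussian noise standard deviation (default 0.05).
#' @param boneIntensity,backgroundIntensity bone and background intensities in
#'   \[0, 1\] (defaults 0.85 / 0.15).
#' @param seed root seed; case `i` derives its stream from `seed + i`.
#' @param enforceSeparability require
#'   `boneIntensity - backgroundIntensity > 3 * noiseSd` (guaranteed contrast;
#'   default TRUE). Set to FALSE to deliberately generate low-contrast data.
#' @return a validated [PhantomConfig-class].
#' @examples
#' cfg <- phantomConfig(nCases = 2, nSlices = 20, imageSize = 32, noiseSd = 0)
#' case <- generateCase(cfg, 1)
#' nSlices(case$sequence)
#' @export
phantomConfig <- function(nCases, nSlices = 160L, imageSize = 384L,
                          compartments = NULL, noiseSd = 0.05,
                          boneIntensity = 0.85, backgroundIntensity = 0.15,
                          seed = 1L, enforceSeparability = TRUE) {
  nSlices <- as.integer(nSlices)
  if (is.null(compartments)) compartments <- .defaultCompartments(nSlices)
  if (enforceSeparability &&
      boneIntensity - backgroundIntensity <= 3 * noiseSd)
    stop("boneIntensity - backgroundIntensity must exceed 3 * noiseSd ",
         "(set enforceSeparability = FALSE to override)")
  .checkDisjointRegions(compartments)
  new("PhantomConfig", nCases = as.integer(nCases), nSlices = nSlices,
      imageSize = as.integer(imageSize), compartments = compartments,
      noiseSd = as.numeric(noiseSd), boneIntensity = as.numeric(boneIntensity),
      backgroundIntensity = as.numeric(backgroundIntensity),
      seed = as.integer(seed))
}

# Run fn() under a seeded, self-contained RNG stream, restoring caller state.
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Filled ellipse on an n x n pixel grid; centre in pixel units, radii >= ~1.2
# so at least one pixel centre always falls inside.
.ellipseMask <- function(n, cx, cy, rx, ry) {
  xs <- seq_len(n)
  dx2 <- ((xs - cx) / rx)^2   # column (x) offsets
  dy2 <- ((xs - cy) / ry)^2   # row (y) offsets
  outer(dy2, dx2, "+") <= 1
}

#' Generate one synthetic phantom case
#'
#' Deterministically generates case `caseIndex` of the family described by
#' `config`: an [MRISequence-class] plus ground-truth [MaskSequence-class]
#' stacks for femur, tibia, patella and their union ("whole"). Each
#' compartment's mask is non-empty exactly on its drawn `[start, end]` slice
#' interval; masks are pairwise disjoint on every slice. The same
#' `(seed, caseIndex)` always yields bit-identical output.
#'
#' @param config a [PhantomConfig-class].
#' @param caseIndex 1-based case index, `<= config@nCases`.
#' @return list with elements `sequence` ([MRISequence-class]), `masks`
#'   (named list of [MaskSequence-class]: femur, tibia, patella, whole) and
#'   `info` (per-compartment drawn start/end slice indices).
#' @export
generateCase <- function(config, caseIndex) {
  stopifnot(is(config, "PhantomConfig"))
  caseIndex <- as.integer(caseIndex)
  if (caseIndex < 1L || caseIndex > config@nCases)
    stop("caseIndex must be in 1..nCases")
  n <- config@imageSize
  S <- config@nSlices
  .withSeed(config@seed + caseIndex, function() {
    masks <- list()
    info <- list()
    union <- array(0, c(n, n, S))
    for (nm in names(config@compartments)) {
      cp <- config@compartments[[nm]]
      pick <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
      start <- pick(cp$startRange[1], cp$startRange[2])
      end <- pick(cp$endRange[1], cp$endRange[2])
      cx0 <- runif(1, cp$cx[1], cp$cx[2]) * n
      cy0 <- runif(1, cp$cy[1], cp$cy[2]) * n
      rx0 <- runif(1, cp$rx[1], cp$rx[2]) * n
      ry0 <- runif(1, cp$ry[1], cp$ry[2]) * n
      phase <- runif(1, 0, 2 * pi)
      m <- array(0, c(n, n, S))
      mid <- (start + end) / 2
      half <- (end - start) / 2
      for (k in start:end) {
        u <- (k - mid) / (half + 0.5)
        s <- sqrt(max(0, 1 - u^2))
        # taper to a small sliver at the ends, never to nothing
        rx <- max(2.5, s * rx0)
        ry <- max(2.5, s * ry0)
        dshift <- cp$drift * n * sin(pi * (k - start) / (end - start + 1) + phase)
        m[, , k] <- .ellipseMask(n, cx0 + dshift, cy0 + dshift, rx, ry)
      }
      masks[[nm]] <- m
      info[[nm]] <- list(start = start, end = end)
      union <- pmax(union, m)
    }
    img <- config@backgroundIntensity +
      (config@boneIntensity - config@backgroundIntensity) * union
    if (config@noiseSd > 0) {
      img <- img + array(rnorm(length(img), 0, config@noiseSd), dim(img))
      img <- pmin(pmax(img, 0), 1)
    }
    id <- sprintf("phantom_%03d", caseIndex)
    out <- lapply(names(masks), function(nm) MaskSequence(id, nm, masks[[nm]]))
    names(out) <- names(masks)
    out$whole <- MaskSequence(id, "whole", union)
    list(sequence = MRISequence(id, img), masks = out, info = info)
  })
}

#' Generate a synthetic phantom dataset
#'
#' Generates all `config@nCases` cases (see [generateCase()]) and optionally
#' writes them to disk together with a plain-text manifest recording, per
#' case, the slice count and each compartment's drawn start/end slice.
#'
#' @param config a [PhantomConfig-class].
#' @param dir optional output directory; when given, each case is written via
#'   [writeSequence()]/[writeMasks()] in `format` and a `manifest.txt` is
#'   created.
#' @param format on-disk format, one of `"png_stack"`, `"nifti"`, `"rds"`.
#' @return invisible list of cases (as from [generateCase()]).
#' @export
generateDataset <- function(config, dir = NULL,
                            format = c("png_stack", "nifti", "rds")) {
  stopifnot(is(config, "PhantomConfig"))
  format <- match.arg(format)
  cases <- lapply(seq_len(config@nCases), function(i) generateCase(config, i))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    lines <- character(0)
    for (cs in cases) {
      id <- caseId(cs$sequence)
      caseDir <- file.path(dir, id)
      writeSequence(cs$sequence, file.path(caseDir, "image"), format)
      for (nm in names(cs$masks))
        writeMasks(cs$masks[[nm]], file.path(caseDir, paste0("mask_", nm)),
                   format)
      ivals <- vapply(names(cs$info), function(nm)
        sprintf("%s:%d-%d", nm, cs$info[[nm]]$start, cs$info[[nm]]$end),
        character(1))
      lines <- c(lines, paste(id, nSlices(cs$sequence),
                              paste(ivals, collapse = " ")))
    }
    writeLines(lines, file.path(dir, "manifest.txt"))
  }
  invisible(cases)
}
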