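#' @include accessors.R
NULL

.IO_FORMATS <- c("png_stack", "nifti", "rds", "npz", "dicom_dir")

.unsupportedFormat <- function(format) {
  stop(sprintf(
    "format '%s' is not supported by this build; convert the series to NIfTI (e.g. with dcm2niix) or use png_stack/rds",
    format), call. = FALSE)
}

# Order PNG stack files by the numeric part of their filename.
.orderedPngs <- function(path) {
  files <- list.files(path, pattern = "\\.png$", full.names = TRUE)
  if (!length(files)) stop(sprintf("no PNG files found in '%s'", path))
  num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
  if (any(is.na(num))) stop(sprintf(
    "cannot order PNG stack in '%s': filenames carry no slice number", path))
  files[order(num)]
}

.readPngGrid <- function(f) {
  g <- png::readPNG(f)
  if (length(dim(g)) == 3L) g <- g[, , 1L]  # grayscale written as RGB(A)
  g
}

#' Read a slice stack from disk
#'
#' Reads an ordered stack of 2D slices as an [MRISequence-class]. PNG stacks
#' are ordered by the numeric part of the filename; NIfTI volumes keep their
#' stored slice order and voxel spacing; `rds` bundles round-trip bit-exactly.
#' DICOM series and NPZ bundles are recognised tokens but not supported by
#' this build (a clear error points at NIfTI conversion).
#'
#' @param path file (nifti, rds) or directory (png_stack).
#' @param format one of `"png_stack"`, `"nifti"`, `"rds"`.
#' @param caseId case identifier; defaults to the basename of `path`.
#' @param spacing voxel spacing override; default: metadata when present
#'   (NIfTI), else `c(1, 1, 1)`.
#' @return an [MRISequence-class].
#' @export
readSequence <- function(path, format = c("png_stack", "nifti", "rds", "npz",
                                          "dicom_dir"),
                         caseId = NULL, spacing = NULL) {
  format <- match.arg(format)
  if (format %in% c("npz", "dicom_dir")) .unsupportedFormat(format)
  if (is.null(caseId)) caseId <- sub("\\.(nii(\\.gz)?|rds)$", "", basename(path))
  if (format == "png_stack") {
    files <- .orderedPngs(path)
    grids <- lapply(files, .readPngGrid)
    dims <- vapply(grids, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop(sprintf("inconsistent slice shape in '%s' (first offender: %s)",
                   path, basename(files[[which(dims[1, ] != dims[1, 1] |
                                               dims[2, ] != dims[2, 1])[1]]])))
    return(MRISequence(caseId, simplify2array(grids),
                       spacing %||% c(1, 1, 1)))
  }
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim(img))
    if (length(dim(arr)) != 3L) stop(sprintf("'%s' is not a 3-d volume", path))
    sp <- spacing %||% abs(RNifti::pixdim(img))[seq_len(3)]
    if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
    return(MRISequence(caseId, arr, sp))
  }
  # rds bundle
  b <- readRDS(path)
  MRISequence(b$caseId %||% caseId, b$data, spacing %||% b$spacing %||% c(1, 1, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a slice stack or mask stack to disk
#'
#' `writeSequence` writes intensities; `writeMasks` writes a binary mask stack
#' (PNG masks are stored as 0/255 and re-binarised on read). The `rds` format
#' round-trips intensities bit-exactly; PNG intensities are quantised to
#' 8-bit (masks round-trip exactly in every format).
#'
#' @param seq an [MRISequence-class].
#' @param mask a [MaskSequence-class].
#' @param path target file (nifti, rds) or directory (png_stack).
#' @param format one of `"png_stack"`, `"nifti"`, `"rds"`.
#' @return invisibly, the path written.
#' @export
writeSequence <- function(seq, path, format = c("png_stack", "nifti", "rds",
                                                "npz", "dicom_dir")) {
  stopifnot(is(seq, "MRISequence"))
  format <- match.arg(format)
  if (format %in% c("npz", "dicom_dir")) .unsupportedFormat(format)
  .writeStack(sliceData(seq), caseId(seq), spacing(seq), path, format)
}

#' @rdname writeSequence
#' @export
writeMasks <- function(mask, path, format = c("png_stack", "nifti", "rds",
                                              "npz", "dicom_dir")) {
  stopifnot(is(mask, "MaskSequence"))
  format <- match.arg(format)
  if (format %in% c("npz", "dicom_dir")) .unsupportedFormat(format)
  .writeStack(sliceData(mask), caseId(mask), c(1, 1, 1), path, format,
              compartment = compartment(mask))
}

.writeStack <- function(arr, caseId, spacing, path, format,
                        compartment = NULL) {
  if (format == "png_stack") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(dim(arr)[3]))
      png::writePNG(pmin(pmax(arr[, , k], 0), 1),
                    file.path(path, sprintf("slice_%04d.png", k)),
                    dpi = NULL)
  } else if (format == "nifti") {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    saveRDS(list(caseId = caseId, data = arr, spacing = spacing,
                 compartment = compartment), path)
  }
  invisible(path)
}

#' Read a binary mask stack
#'
#' Counterpart of [writeMasks()]; values are re-binarised at 0.5 on read.
#'
#' @inheritParams readSequence
#' @param compartment compartment label to attach.
#' @return a [MaskSequence-class].
#' @export
readMasks <- function(path, format = c("png_stack", "nifti", "rds", "npz",
                                       "dicom_dir"),
                      compartment = "whole", caseId = NULL) {
  format <- match.arg(format)
  seq <- readSequence(path, format, caseId = caseId)
  comp <- compartment
  if (format == "rds") {
    b <- readRDS(path)
    if (!is.null(b$compartment)) comp <- b$compartment
  }
  MaskSequence(caseId(seq), comp,
               array(as.numeric(sliceData(seq) > 0.5), dim(sliceData(seq))))
}

#' Per-case min-max intensity normalisation
#'
#' Scales the whole case (not each slice) to \[0, 1\], preserving inter-slice
#' intensity relationships within one scan. A constant-valued case maps to all
#' zeros.
#'
#' @param seq an [MRISequence-class].
#' @return the normalised [MRISequence-class].
#' @export
normalizeIntensity <- function(seq) {
  stopifnot(is(seq, "MRISequence"))
  x <- sliceData(seq)
  rng <- range(x)
  x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1])
       else array(0, dim(x))
  MRISequence(caseId(seq), x, spacing(seq))
}

#' Crop a fixed margin from all four borders
#'
#' Removes `margin` pixels from the top, bottom, left and right of a 2D grid
#' or of every slice of a sequence/mask stack; a 384x384 grid cropped with
#' margin 16 becomes 352x352.
#'
#' @param x a matrix, 3-d array, [MRISequence-class] or [MaskSequence-class].
#' @param margin non-negative integer, `2 * margin < min(height, width)`.
#' @return the cropped object, same type as the input.
#' @export
cropBorders <- function(x, margin) {
  margin <- as.integer(margin)
  if (margin < 0L) stop("margin must be non-negative")
  if (is(x, "MRISequence"))
    return(MRISequence(caseId(x), cropBorders(sliceData(x), margin),
                       spacing(x)))
  if (is(x, "MaskSequence"))
    return(MaskSequence(caseId(x), compartment(x),
                        cropBorders(sliceData(x), margin)))
  d <- dim(x)
  if (2L * margin >= min(d[1], d[2]))
    stop(sprintf("margin %d too large for a %dx%d grid", margin, d[1], d[2]))
  if (margin == 0L) return(x)
  rows <- (margin + 1L):(d[1] - margin)
  cols <- (margin + 1L):(d[2] - margin)
  if (length(d) == 3L) x[rows, cols, , drop = FALSE] else x[rows, cols]
}

#' Resize a 2D grid
#'
#' Bilinear interpolation for intensity grids; nearest-neighbour followed by
#' re-binarisation at 0.5 for masks (so outputs stay in \{0, 1\}).
#'
#' @param grid numeric matrix.
#' @param size target square size in pixels.
#' @param kind `"intensity"` or `"mask"`.
#' @return a `size` x `size` matrix.
#' @export
resizeGrid <- function(grid, size, kind = c("intensity", "mask")) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 1L) stop("size must be >= 1")
  if (all(dim(grid) == c(size, size)) && kind == "mask") return(grid)
  out <- EBImage::resize(EBImage::Image(grid), w = size, h = size,
                         filter = if (kind == "mask") "none" else "bilinear")
  out <- EBImage::imageData(out)
  if (kind == "mask") out <- (out > 0.5) + 0
  out
}

.halfUp <- function(x) floor(x + 0.5)

#' Case-level train/validation/test split
#'
#' Randomly partitions case ids into train/validation/test sets. Validation
#' and test sizes are `round(n * fraction)` (half-up); the training set takes
#' the remainder, so 99 cases at (0.70, 0.15, 0.15) give 69/15/15. The shuffle
#' is deterministic given `seed` and splitting is by case id only.
#'
#' @param caseIds character vector of case ids (unique).
#' @param fractions length-3 positive fractions (train, val, test) summing to
#'   1 (tolerance 1e-9).
#' @param seed shuffle seed.
#' @return a [CaseSplit-class].
#' @export
splitCases <- function(caseIds, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  caseIds <- as.character(caseIds)
  if (anyDuplicated(caseIds)) stop("case ids must be unique")
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("fractions must be 3 positive numbers")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- length(caseIds)
  if (n < 3L) stop("need at least 3 cases to form three non-empty sets")
  nVal <- .halfUp(n * fractions[2])
  nTest <- .halfUp(n * fractions[3])
  nTrain <- n - nVal - nTest
  if (nTrain < 1L || nVal < 1L || nTest < 1L)
    stop("split produces an empty set; use more cases")
  ids <- .withSeed(seed, function() sample(caseIds))
  new("CaseSplit",
      trainIds = ids[seq_len(nTrain)],
      valIds = ids[nTrain + seq_len(nVal)],
      testIds = ids[nTrain + nVal + seq_len(nTest)])
}

#' Read/write a phantom dataset manifest
#'
#' The manifest is a plain-text file with one case per line:
#' `case_id n_slices compartment:start-end ...`.
#'
#' @param file path to `manifest.txt`.
#' @return a data.frame with columns `caseId`, `nSlices` and
#'   `<compartment>Start`/`<compartment>End` per listed compartment.
#' @export
readManifest <- function(file) {
  lines <- readLines(file)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), function(tok) {
    out <- list(caseId = tok[1], nSlices = as.integer(tok[2]))
    for (iv in tok[-(1:2)]) {
      p <- strsplit(iv, "[:-]")[[1]]
      out[[paste0(p[1], "Start")]] <- as.integer(p[2])
      out[[paste0(p[1], "End")]] <- as.integer(p[3])
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
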