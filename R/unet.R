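#' @include AllGenerics.R
#' @useDynLib kneeseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Architecture specification of the modified U-net
#'
#' The modified U-net keeps the classic contraction/expansion layout but
#' same-pads every 3x3 convolution (so the output image size equals the input
#' size), upsamples with learned 2x2 stride-2 transposed convolutions, and
#' ends with a 1x1 convolution under a sigmoid, producing a per-pixel
#' probability map. There is no batch normalisation and no dropout. With the
#' defaults (1 input channel, 1 output channel, base width 64, depth 5) the
#' network has 23 convolutional layers and 31,030,593 trainable parameters.
#'
#' `countParameters` evaluates the closed-form layer sum (3x3 conv:
#' `9*Cin*Cout + Cout`; 2x2 transposed conv: `4*Cin*Cout + Cout`; 1x1 conv:
#' `Cin*Cout + Cout`); `countConvLayers` counts every weight-bearing
#' convolution: `2*(depth-1) + 2 + 3*(depth-1) + 1`.
#'
#' @param inChannels,outChannels input/output channels (default 1).
#' @param baseWidth channels at the highest resolution level (default 64).
#' @param depth number of resolution levels including the bottleneck
#'   (default 5).
#' @param inputSize square input size in pixels; must be divisible by
#'   `2^(depth-1)`. Default 352 (the segmentation resolution); the detection
#'   models use 128.
#' @param spec a [UNetSpec-class].
#' @return `unetSpec` returns a validated [UNetSpec-class]; the counters
#'   return integers.
#' @examples
#' countParameters(unetSpec())   # 31030593
#' countConvLayers(unetSpec())   # 23
#' @export
unetSpec <- function(inChannels = 1L, outChannels = 1L, baseWidth = 64L,
                     depth = 5L, inputSize = 352L) {
  new("UNetSpec", inChannels = as.integer(inChannels),
      outChannels = as.integer(outChannels), baseWidth = as.integer(baseWidth),
      depth = as.integer(depth), inputSize = as.integer(inputSize),
      finalActivation = "sigmoid")
}

# Per-layer (Cin, Cout, kind) inventory, in forward order.
.unetLayerTable <- function(spec) {
  D <- spec@depth
  width <- function(l) spec@baseWidth * 2L^(l - 1L)
  rows <- list()
  add <- function(kind, cin, cout)
    rows[[length(rows) + 1L]] <<- list(kind = kind, cin = cin, cout = cout)
  prev <- spec@inChannels
  for (l in seq_len(D - 1L)) {
    add("conv3", prev, width(l)); add("conv3", width(l), width(l))
    prev <- width(l)
  }
  add("conv3", prev, width(D)); add("conv3", width(D), width(D))
  for (l in rev(seq_len(D - 1L))) {
    add("upconv2", width(l + 1L), width(l))
    add("conv3", 2L * width(l), width(l)); add("conv3", width(l), width(l))
  }
  add("conv1", width(1L), spec@outChannels)
  rows
}

#' @rdname unetSpec
setMethod("countParameters", "UNetSpec", function(spec) {
  per <- vapply(.unetLayerTable(spec), function(r) {
    switch(r$kind,
           conv3 = 9 * r$cin * r$cout + r$cout,
           upconv2 = 4 * r$cin * r$cout + r$cout,
           conv1 = r$cin * r$cout + r$cout)
  }, numeric(1))
  as.integer(sum(per))
})

#' @rdname unetSpec
setMethod("countConvLayers", "UNetSpec", function(spec) {
  length(.unetLayerTable(spec))
})

# flat parameter names ------------------------------------------------------

.encNames <- function(l) sprintf("enc%d_%s", l, c("K1", "b1", "K2", "b2"))
.botNames <- function() sprintf("bot_%s", c("K1", "b1", "K2", "b2"))
.decNames <- function(l) sprintf("dec%d_%s", l, c("U", "bu", "K1", "b1", "K2", "b2"))

#' Build a modified U-net
#'
#' Instantiates the network described by a [UNetSpec-class]. Convolution
#' kernels use He-uniform initialisation (`limit = sqrt(6 / fan_in)`), biases
#' start at zero; initialisation is deterministic given `seed`.
#'
#' @param spec a [UNetSpec-class].
#' @param seed initialisation seed.
#' @return a [UNetModel-class].
#' @export
buildUnet <- function(spec, seed = 1L) {
  stopifnot(is(spec, "UNetSpec"))
  validObject(spec)
  D <- spec@depth
  width <- function(l) spec@baseWidth * 2L^(l - 1L)
  .withSeed(seed, function() {
    he <- function(nr, nc, fanIn) {
      lim <- sqrt(6 / fanIn)
      matrix(runif(nr * nc, -lim, lim), nr, nc)
    }
    p <- list()
    prev <- spec@inChannels
    for (l in seq_len(D - 1L)) {
      w <- width(l)
      nm <- .encNames(l)
      p[[nm[1]]] <- he(9L * prev, w, 9 * prev)
      p[[nm[2]]] <- numeric(w)
      p[[nm[3]]] <- he(9L * w, w, 9 * w)
      p[[nm[4]]] <- numeric(w)
      prev <- w
    }
    wD <- width(D)
    nm <- .botNames()
    p[[nm[1]]] <- he(9L * prev, wD, 9 * prev)
    p[[nm[2]]] <- numeric(wD)
    p[[nm[3]]] <- he(9L * wD, wD, 9 * wD)
    p[[nm[4]]] <- numeric(wD)
    for (l in rev(seq_len(D - 1L))) {
      w <- width(l)
      nm <- .decNames(l)
      p[[nm[1]]] <- he(width(l + 1L), 4L * w, width(l + 1L))
      p[[nm[2]]] <- numeric(w)
      p[[nm[3]]] <- he(9L * 2L * w, w, 9 * 2 * w)
      p[[nm[4]]] <- numeric(w)
      p[[nm[5]]] <- he(9L * w, w, 9 * w)
      p[[nm[6]]] <- numeric(w)
    }
    p[["fin_K"]] <- he(width(1L), spec@outChannels, width(1L))
    p[["fin_b"]] <- numeric(spec@outChannels)
    new("UNetModel", spec = spec, params = p, seed = as.integer(seed))
  })
}

#' Enumerate a model's trainable parameters
#'
#' Sums the lengths of every weight matrix and bias vector of an instantiated
#' [UNetModel-class]; the cross-check counterpart of the closed-form
#' [countParameters()].
#'
#' @param model a [UNetModel-class].
#' @return integer total number of trainable parameters.
#' @export
enumerateParameters <- function(model) {
  stopifnot(is(model, "UNetModel"))
  as.integer(sum(vapply(model@params, length, numeric(1))))
}

# forward / backward --------------------------------------------------------

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Forward pass over a batch x of shape (H, W, inChannels, N).
# Returns logits z, probabilities prob, and (optionally) the cache needed for
# the backward pass.
.unetForward <- function(model, x, wantCache = FALSE) {
  p <- model@params
  D <- model@spec@depth
  cache <- list(enc = vector("list", D - 1L), dec = vector("list", D - 1L))
  cur <- x
  for (l in seq_len(D - 1L)) {
    nm <- .encNames(l)
    a1 <- .relu(conv3x3_forward(cur, p[[nm[1]]], p[[nm[2]]]))
    a2 <- .relu(conv3x3_forward(a1, p[[nm[3]]], p[[nm[4]]]))
    pool <- maxpool2_forward(a2)
    if (wantCache) cache$enc[[l]] <- list(x = cur, a1 = a1, a2 = a2,
                                          idx = pool$idx)
    else cache$enc[[l]] <- list(a2 = a2)
    cur <- pool$y
  }
  nm <- .botNames()
  b1 <- .relu(conv3x3_forward(cur, p[[nm[1]]], p[[nm[2]]]))
  b2 <- .relu(conv3x3_forward(b1, p[[nm[3]]], p[[nm[4]]]))
  if (wantCache) cache$bot <- list(x = cur, a1 = b1, a2 = b2)
  cur <- b2
  for (l in rev(seq_len(D - 1L))) {
    nm <- .decNames(l)
    up <- upconv2x2_forward(cur, p[[nm[1]]], p[[nm[2]]])
    skip <- cache$enc[[l]]$a2
    cat <- .catChannels(skip, up)   # encoder features first
    a1 <- .relu(conv3x3_forward(cat, p[[nm[3]]], p[[nm[4]]]))
    a2 <- .relu(conv3x3_forward(a1, p[[nm[5]]], p[[nm[6]]]))
    if (wantCache) cache$dec[[l]] <- list(x = cur, cat = cat, a1 = a1, a2 = a2)
    cur <- a2
  }
  z <- conv1x1_forward(cur, p[["fin_K"]], p[["fin_b"]])
  if (wantCache) cache$fin <- list(x = cur)
  list(prob = .sigmoid(z), logits = z, cache = if (wantCache) cache)
}

# Backward pass: dlogits is the loss gradient w.r.t. the pre-sigmoid output.
# Returns gradients as a flat named list parallel to model@params.
.unetBackward <- function(model, cache, dlogits) {
  p <- model@params
  D <- model@spec@depth
  g <- list()
  gf <- conv1x1_backward(cache$fin$x, p[["fin_K"]], dlogits)
  g[["fin_K"]] <- gf$dK; g[["fin_b"]] <- gf$db
  dcur <- gf$dx
  dskip <- vector("list", D - 1L)
  for (l in seq_len(D - 1L)) {      # decoder levels, innermost-first = level 1
    nm <- .decNames(l)
    cc <- cache$dec[[l]]
    dz2 <- dcur * (cc$a2 > 0)
    g2 <- conv3x3_backward(cc$a1, p[[nm[5]]], dz2)
    g[[nm[5]]] <- g2$dK; g[[nm[6]]] <- g2$db
    dz1 <- g2$dx * (cc$a1 > 0)
    g1 <- conv3x3_backward(cc$cat, p[[nm[3]]], dz1)
    g[[nm[3]]] <- g1$dK; g[[nm[4]]] <- g1$db
    nSkip <- dim(cache$enc[[l]]$a2)[3]
    dcat <- g1$dx
    dskip[[l]] <- dcat[, , seq_len(nSkip), , drop = FALSE]
    dup <- dcat[, , nSkip + seq_len(dim(dcat)[3] - nSkip), , drop = FALSE]
    gu <- upconv2x2_backward(cc$x, p[[nm[1]]], dup)
    g[[nm[1]]] <- gu$dU; g[[nm[2]]] <- gu$db
    dcur <- gu$dx
  }
  nm <- .botNames()
  dz2 <- dcur * (cache$bot$a2 > 0)
  g2 <- conv3x3_backward(cache$bot$a1, p[[nm[3]]], dz2)
  g[[nm[3]]] <- g2$dK; g[[nm[4]]] <- g2$db
  dz1 <- g2$dx * (cache$bot$a1 > 0)
  g1 <- conv3x3_backward(cache$bot$x, p[[nm[1]]], dz1)
  g[[nm[1]]] <- g1$dK; g[[nm[2]]] <- g1$db
  dcur <- g1$dx
  for (l in rev(seq_len(D - 1L))) {  # encoder levels, deepest first
    nm <- .encNames(l)
    cc <- cache$enc[[l]]
    da2 <- maxpool2_backward(dcur, cc$idx, dim(cc$a2)[1], dim(cc$a2)[2]) +
      dskip[[l]]
    dz2 <- da2 * (cc$a2 > 0)
    g2 <- conv3x3_backward(cc$a1, p[[nm[3]]], dz2)
    g[[nm[3]]] <- g2$dK; g[[nm[4]]] <- g2$db
    dz1 <- g2$dx * (cc$a1 > 0)
    g1 <- conv3x3_backward(cc$x, p[[nm[1]]], dz1)
    g[[nm[1]]] <- g1$dK; g[[nm[2]]] <- g1$db
    dcur <- g1$dx
  }
  g
}

#' Predict per-pixel probabilities for a slice batch
#'
#' Runs the network forward on a `(H, W, 1, N)` batch (or a single `(H, W)`
#' matrix) and returns the sigmoid probability maps, processing the batch in
#' chunks to bound memory.
#'
#' @param model a [UNetModel-class], or any function mapping an image batch to
#'   a probability batch of the same shape (oracle models).
#' @param x image batch `(H, W, 1, N)` array or a single matrix.
#' @param chunk slices per forward pass (default 16).
#' @return probability array with the same shape as `x`.
#' @export
predictProb <- function(model, x, chunk = 16L) {
  single <- is.matrix(x)
  if (single) x <- array(x, c(dim(x), 1L, 1L))
  if (is.function(model)) return(if (single) model(x)[, , 1, 1] else model(x))
  stopifnot(is(model, "UNetModel"))
  d <- dim(x)
  if (d[1] != model@spec@inputSize || d[2] != model@spec@inputSize)
    stop(sprintf("input is %dx%d but the model expects %dx%d",
                 d[1], d[2], model@spec@inputSize, model@spec@inputSize))
  out <- array(0, d)
  for (i in seq(1L, d[4], by = chunk)) {
    j <- min(d[4], i + chunk - 1L)
    out[, , , i:j] <- .unetForward(model, x[, , , i:j, drop = FALSE])$prob
  }
  if (single) out[, , 1, 1] else out
}
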