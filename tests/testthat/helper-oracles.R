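# Independent brute-force oracles used across the metric tests. These
# deliberately avoid the package's pooled-count code path: masks are flattened
# to explicit voxel index sets and compared with set operations.

oracleOverlap <- function(gt, pred) {
  sg <- which(as.vector(gt) > 0.5)
  sm <- which(as.vector(pred) > 0.5)
  list(nG = length(sg), nM = length(sm), nInter = length(intersect(sg, sm)),
       nUnion = length(union(sg, sm)))
}

oracleDice <- function(gt, pred) {
  o <- oracleOverlap(gt, pred)
  if (o$nG + o$nM == 0) 1 else 2 * o$nInter / (o$nG + o$nM)
}

oracleSI <- function(gt, pred) {
  o <- oracleOverlap(gt, pred)
  if (o$nUnion == 0) 1 else o$nInter / o$nUnion
}

randomMask <- function(dims, p) {
  array(rbinom(prod(dims), 1, p), dims)
}

# Oracle "model": thresholds the image at the phantom's midpoint intensity.
# On a separable phantom this recovers the ground-truth whole-knee mask, so it
# stands in for a perfectly trained network in pipeline tests.
thresholdOracle <- function(midpoint = 0.5) {
  function(x) {
    out <- (x > midpoint) + 0
    dim(out) <- dim(x)
    out
  }
}
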