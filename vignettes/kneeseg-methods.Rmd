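---
title: "Two-stage knee bone detection and segmentation: models and methods"
author: "kneeseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage knee bone detection and segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A 3D knee MRI (for instance a DESS sequence acquired for osteoarthritis
studies) is an ordered stack of 2D slices — typically 160 slices of
384×384 pixels for one knee. Each bone compartment (femur, tibia, patella)
appears only on a contiguous sub-interval of those slices: the femur might be
visible from slice 22 to slice 134, the tibia from 30 to 136, the patella
from 50 to 115, and those intervals differ between knees. A segmentation
network trained on all slices wastes capacity on bone-free images and tends
to hallucinate bone on them; a network trained on bone slices only cannot by
itself decide *which* slices carry bone.

`kneeseg` therefore implements a fully automatic two-stage method:

1. a **slice-presence detection network** marks, per slice, whether the
   compartment appears at all (an all-black output map means "no bone");
2. a **segmentation network** delineates the bone on the selected slices at
   full resolution.

Both stages are the same modified U-net; they differ only in input
resolution (detection runs on slices resized to 128×128 for speed,
segmentation at the cropped acquisition resolution of 352×352) and in
training loss.

## The modified U-net

The network keeps the classic encoder–decoder layout with skip connections
and modifies it in four ways: every 3×3 convolution is *same-padded*, so the
output image has exactly the input size (the unpadded original loses border
pixels at every layer); optimisation uses Adam instead of plain SGD; the head
is a 1×1 convolution under a **sigmoid**, producing a per-pixel probability
map; and the training loss is **binary cross-entropy** for detection and
**soft Dice (negative Dice)** for segmentation,

$$L_{\mathrm{softDice}}(p, t) \;=\; -\,\frac{2\sum_i p_i t_i + \varepsilon}
       {\sum_i p_i + \sum_i t_i + \varepsilon},$$

with smoothing constant $\varepsilon$ (default 1) making the empty/empty
case well-defined. On binary predictions this is exactly the negative Dice
coefficient as $\varepsilon \to 0$, a link the test suite verifies against a
brute-force voxel-set oracle.

With depth 5 (four encoder levels plus bottleneck), base width 64 and one
input/output channel the network has **23 convolutional layers** — counting
the 2×2 transposed-convolution upsamplers and the final 1×1 head — and
**31,030,593 trainable parameters**. Two architectural choices are forced by
that figure: there is *no* batch normalisation or dropout, and upsampling is
a *learned* 2×2 transposed convolution rather than parameter-free
interpolation. `countParameters()` evaluates the closed-form sum
(3×3 conv: $9C_{in}C_{out}+C_{out}$; transposed 2×2:
$4C_{in}C_{out}+C_{out}$; 1×1: $C_{in}C_{out}+C_{out}$), and
`enumerateParameters()` cross-checks it against the weights of the
instantiated model.

Choices the architecture description leaves open, fixed here for
determinism: He-uniform kernel initialisation with zero biases (standard for
ReLU networks), seeded; skip concatenation order is
`[encoder features, upsampled features]` (either order gives the same
parameter count); the transposed convolution itself carries no activation,
ReLU follows the two 3×3 convolutions of each decoder level.

### The in-package CNN engine

No deep-learning framework is attached: the package carries its own compact
engine — im2col + GEMM same-padded 3×3 convolution, 1×1 convolution, 2×2
max-pooling, 2×2 stride-2 transposed convolution, all with hand-derived
backward passes in RcppArmadillo, plus an R-level Adam loop. Every backward
kernel is verified against central finite differences in the test suite
(relative error below $10^{-3}$ at $h = 10^{-6}$, typically
$\sim 10^{-6}$). Tensors are `(H, W, C, N)` arrays in R's column-major
layout so each channel plane is contiguous.

## Training schedule

`trainConfig()` defaults mirror the full-scale reference schedule: Adam with
learning rate $10^{-5}$ ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\varepsilon = 10^{-8}$), batch size 16, at most 300 epochs, early stopping
after 35 epochs without improvement (the midpoint of the quoted 30–40
range), monitoring validation Dice for segmentation and per-slice validation
detection accuracy for detection. Weights from the best-monitored epoch are
restored at stop — the reference description does not say whether best or
last weights were kept; best-epoch restoration is the standard companion of
early stopping and is what `trainModel()` does. No data augmentation is
applied. A non-finite loss aborts training with a diagnostic rather than
silently continuing.

## Preprocessing

All images and masks are cropped 16 pixels from every border
(384×384 → 352×352), because manual labels do not reach the image edge.
Intensities are min–max normalised *per case* (not per slice), preserving
inter-slice relationships within one scan; a constant case maps to zeros.
Detection inputs are resized bilinearly; masks are resized nearest-neighbour
and re-binarised at 0.5 so they stay strictly binary. The case-level split
uses half-up rounding for the validation and test sizes with the remainder
going to training, which reproduces 99 → 69/15/15 cases
(11,040/2,400/2,400 slices at 160 slices per case). Slices are indexed
1-based throughout, the R convention.

## Evaluation

Detection is scored at the slice level: TP/TN/FP/FN per the all-black-map
convention, then recall, precision, and accuracy (a percentage). Segmentation
is scored **at the case level**: the ground-truth and predicted bone pixel
sets are pooled over all slices of a case into 3D sets $S_g$ and $S_m$
before any ratio is formed:

$$\mathrm{Dice} = \frac{2|S_g \cap S_m|}{|S_g| + |S_m|},\qquad
  \mathrm{SI} = \frac{|S_g \cap S_m|}{|S_g \cup S_m|},\qquad
  \mathrm{TPR} = \frac{|S_g \cap S_m|}{|S_g|},$$
$$\mathrm{FPR} = \frac{|S_g \cup S_m| - |S_g|}{|S_g|},\qquad
  \mathrm{FNR} = 1 - \mathrm{TPR}.$$

Aggregates are unweighted means of per-case scores. Degenerate conventions:
an empty/empty case scores Dice = SI = 1 with a flag (automatic detection can
produce such states; they are reported, not hidden); zero-denominator
detection metrics return `NA` sentinels rather than raising. Bone volume is
the voxel count times the voxel size (spacing is an input, default
1 mm³/voxel, since the acquisition spacing is dataset-specific), and
volume agreement is OLS of predicted on true volume plus squared Pearson
correlation. The ablation comparison (automatic vs. manual slice selection on
the same test cases) is a *paired* two-tailed Student's t-test — the two
conditions are evaluated on the same cases, so pairing is the appropriate
form. Display rounding is 2 decimals for percentages and 3 for ratios; raw
values are kept internally.

Two readings of "which slices to segment" are supported and reported:
`per_slice` (segment exactly the detector-positive slices — matches the
per-slice FP/FN accounting of the detection table) and `fill_range`
(segment everything between the first and last positive slice — matches the
"all the slices in between" narrative). `per_slice` is the default.

## The synthetic phantom

The phantom generator makes the whole pipeline testable without patient
data. Each case is a stack of `nSlices` square slices; each compartment
appears on a contiguous interval drawn per case from configurable windows
(defaults scale the canonical 160-slice anchors: femur ≈ 22–134,
tibia ≈ 30–136, patella ≈ 50–115) as a filled ellipse whose centre drifts
smoothly along the stack and whose radii taper towards the interval ends
(bone appearing/disappearing), never below ~2.5 px so presence is exact.
Compartment centre regions are fixed and non-overlapping — femur upper half,
tibia lower half, patella anterior strip, a coarse mirror of knee anatomy —
so masks are pairwise disjoint by construction and the whole-knee mask is
exactly their union. Intensity is two-level (background 0.15, bone 0.85)
plus additive Gaussian noise (default sd 0.05) clipped to [0, 1]; the
configuration enforces `contrast > 3·noiseSd` unless explicitly overridden.
Randomness derives one stream per case from `seed + caseIndex`, so any case
regenerates bit-identically in isolation.

What the phantom does **not** emulate: MRI physics (bias fields, DESS
contrast, partial-volume effects), anatomical bone shape, cartilage and
menisci, inter-slice intensity drift. Tests passing on phantoms therefore
validate the *pipeline mechanics* — data flow, losses, metrics, training
behaviour, detection/segmentation coupling — not clinical-grade real-data
accuracy.

## Desk-scale study conditions

The end-to-end experiment in the test suite trains real networks on
phantoms at a deliberately small scale, chosen once as this package's study
conditions: 30 cases (split 20/5/5 at fractions 0.70/0.15/0.15), 16 slices
of 64×64 per case, default phantom noise and contrast; base width 8,
depth 5 (485,673 parameters); detection input 32×32; Adam learning rate
$10^{-3}$ — appropriate for a network and dataset this small, where the
full-scale $10^{-5}$/300-epoch schedule would be far from convergence —
batch 16, at most 30 epochs, patience 6 (training saturates well within that
budget at this scale). Against held-out phantom cases the
automatic pipeline is required to reach slice-detection accuracy ≥ 0.95 and
mean case-level Dice ≥ 0.90, and the manual-detection ablation must change
mean Dice by less than 0.05 — thresholds deliberately below full-scale
real-data figures, reflecting the reduced resolution and training budget.

## Known limitations

* DICOM series and NPZ bundles are recognised format tokens but not readable
  in this build; NIfTI, PNG stacks and an R-native `rds` bundle (the
  bit-exact round-trip format) are supported. PNG intensities quantise to
  8-bit; masks round-trip exactly in every format.
* The engine is CPU-only and double-precision; it is sized for desk-scale
  experiments and method validation, not for full-resolution training runs.
* Whole-knee evaluation of the three-individual-models route uses the union
  mask against whole-knee ground truth; overlapping compartment predictions
  are additionally resolved into a label map by model probability with the
  fixed tie order femur > tibia > patella.
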