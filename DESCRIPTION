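Package: kneeseg
Title: Two-Stage Detection and Segmentation of Knee Bones in 3D MRI Slice Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automatic two-stage delineation of knee bone compartments
    (femur, tibia, patella, whole knee) in 3D MRI sequences represented as
    ordered 2D slice stacks. A slice-presence detection network first marks the
    slices in which a bone compartment appears; a segmentation network then
    delineates the bone on the selected slices. Both networks are the same
    modified U-net (same-padded convolutions, sigmoid head, Adam, soft-Dice or
    binary cross-entropy loss) built on the package's own RcppArmadillo CNN
    engine. Includes case-level overlap metrics (Dice, Jaccard similarity,
    TPR/FPR/FNR), bone volume estimation with regression agreement, paired
    comparison tests, slice-stack input/output (PNG stacks, NIfTI), and a
    synthetic knee phantom generator so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'unet.R'
    'losses.R'
    'training.R'
    'volume_io.R'
    'metrics.R'
    'pipeline.R'
    'fit_pipeline.R'
    'cli.R'
    'phantom.R'
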