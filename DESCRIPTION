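Package: skelpatch
Title: Skeleton-Guided 3D Patch Pipeline for Intracranial Aneurysm
    Segmentation in TOF-MRA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patch-based semantic segmentation of intracranial
    aneurysms in time-of-flight magnetic resonance angiography (TOF-MRA).
    Provides synthetic vascular phantoms with known vessel and aneurysm
    ground truth, intensity preprocessing (percentile clipping, z-score
    standardization, multiplicative bias-field correction, isotropic
    resampling), topology-preserving 3D vessel skeletonization by iterative
    thinning under 26-connectivity, ratio-controlled sampling of 3D patches
    along the vessel skeleton, a multi-task 3D U-Net with auxiliary
    patch-level classifiers trained with Dice, Tversky-focal and
    cross-entropy losses, segmentation metrics (Dice similarity
    coefficient, accuracy, sensitivity, specificity, predictive values)
    with aneurysm-size stratification, and an experiment driver for
    normal-to-aneurysm patch ratio ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    optparse
Config/testthat/edition: 3
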