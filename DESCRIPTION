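Package: ctmrsyn
Title: Cross-Modality CT-to-MR Image Synthesis with Paired and Unpaired
    Adversarial Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns a CT-to-MR intensity translation from a mixture of
    registered (paired) and independent (unpaired) axial image slices
    using a dual cycle-consistent generative adversarial model: least
    squares adversarial losses on the unpaired pools, conditional
    log-likelihood adversarial and voxel-wise L1 losses on the
    registered pairs, and cycle-consistency constraints in both
    directions for both data regimes.  Includes Hounsfield-unit
    windowing and training-time augmentation with correct
    paired/unpaired semantics, a residual-block generator and
    dual-head patch discriminators built on an in-package
    convolutional network engine, an alternating-phase trainer with
    checkpointing, slice synthesis, and MAE/PSNR/SSIM evaluation
    reports.  Ships a synthetic two-modality phantom generator so the
    full pipeline is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    jsonlite,
    png,
    RNifti,
    yaml,
    ggplot2,
    generics,
    rlang,
    graphics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
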