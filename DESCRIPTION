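Package: cauchyvessel
Title: Retinal Vessel Segmentation with a Cauchy Matched-Filter Feature Map
    and a U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts blood vessels from colour fundus photographs by
    combining a classical oriented matched filter with a convolutional
    segmentation network. A bank of rotated two-dimensional kernels shaped
    like the Cauchy probability density (the cross-section intensity dip of
    a retinal vessel) is correlated with the contrast-enhanced green
    channel; the per-pixel maximum response replaces the noisy red channel,
    giving a three-plane Cauchy-G-B feature map. A patch-based U-Net is
    trained on 64x64 crops of these maps and full images are segmented by
    non-overlapping tiling. Includes CLAHE/standardization preprocessing,
    flip augmentation, Adam training with a plateau-gated decaying learning
    rate, ROC/threshold-sensitivity evaluation, a synthetic fundus-phantom
    generator with known vessel ground truth, DRIVE-style directory
    readers/writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    withr,
    rlang,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
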