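Package: oarseg
Title: Full-Image 3-D Segmentation of Organs-at-Risk with Residual
    Multi-Resolution Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for fully convolutional 3-D segmentation of
    organs-at-risk (breasts and heart) in CT-like volumes. Implements a
    residual multi-resolution "bib"-shaped network that processes whole
    volumes in a single forward pass, a 3-level valid-convolution U-Net
    baseline with tiled patch-wise inference, soft Jaccard and Dice
    objectives, entropy/shell/mask patch samplers, Nesterov-Adam training
    with tournament selection over random initialisations, trilinear
    spacing harmonisation, Gaussian-smoothing and largest-component
    post-processing, surface-distance and Hausdorff evaluation metrics,
    and paired-t-test model comparison with Bonferroni correction.
    Includes a seeded thorax phantom generator so the whole pipeline runs
    end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
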