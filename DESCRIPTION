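Package: pahisto
Title: Virtual Staining, Nucleus Segmentation and Feature-Fusion
    Classification for Label-Free Photoacoustic Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An interconnected analysis framework for label-free
    photoacoustic histology (PAH) images of tissue sections. Provides
    saliency-constrained contrastive unpaired image translation (E-CUT)
    to render virtual hematoxylin-and-eosin (VHE) stains from grayscale
    PAH tiles, U-Net nucleus segmentation with contour-based morphometry
    (cell area, count, intercellular distance), and a stepwise
    deep-feature-fusion (StepFF) classifier that combines PAH, VHE and
    segmentation feature vectors for binary cancer calls. Includes
    whole-slide tiling with overlap-averaged stitching, integrated
    gradients attribution, Frechet and kernel distance metrics for
    generated images, inter-rater kappa statistics, and a seeded
    synthetic tissue-scene generator used for testing in place of
    non-public clinical data. Networks run on a small built-in
    reverse-mode autodiff engine with C++ convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
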