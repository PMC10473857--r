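Package: grainsight
Title: Multispectral Appearance-Quality Inspection of Rice Grains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale machine-vision pipeline for rice appearance-quality
    inspection from five-channel (RGB plus two near-infrared) backlit images:
    Gaussian denoising and Otsu binarization, roundness-triaged splitting of
    touching grains by an Otsu-clamped gradient watershed, fixed-size
    per-grain crop extraction, and perfect/imperfect grain classification
    with compact VGG- and ResNet-style convolutional networks trained by a
    built-in native engine. Includes a seeded synthetic multispectral scene
    generator with exact per-grain ground truth (instance masks, adhesion
    clusters, defect phenotypes) so that segmentation and classification can
    be exercised and benchmarked without camera hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    png,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'grainsight-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'methods.R'
    'synthetic-scenes.R'
    'preprocess.R'
    'regions.R'
    'watershed.R'
    'stacking.R'
    'nn-engine.R'
    'classifier.R'
    'pipeline.R'
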