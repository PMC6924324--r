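Package: tissueseg
Title: Tissue-Background Segmentation for Whole-Slide Histopathology Images
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Segments tissue from background in multiresolution (pyramidal)
    whole-slide histopathology images. Provides a resolution-agnostic fully
    convolutional neural network trained by class-weighted patch sampling on
    six-label sampling masks, three classical reference segmenters (fixed
    grayscale threshold, Otsu's adaptive threshold, and foreground extraction
    from structure information), polygon annotation handling with cleanup
    rules, shared morphological post-processing, region-level evaluation
    (Dice score, region sensitivity, false-positive statistics, paired
    t-tests), and a synthetic slide generator for fully self-contained
    testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
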