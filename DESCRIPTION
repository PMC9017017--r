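Package: nucleikit
Title: Nuclei Classification, Segmentation and Detection with Recurrent
    Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for cell-nucleus analysis in histopathology-style images:
    densely connected recurrent convolutional classifiers, a recurrent U-Net
    segmenter and a density-regression detector, together with the data
    mechanics around them (patch extraction and merging, point-annotation
    dilation, Gaussian density-surface targets), cell-level evaluation
    (Dice, MSE, optimal point matching, precision/recall/F1, ROC-AUC), a
    seeded generator of microscopy-like synthetic scenes, and a training
    harness with k-fold cross-validation. Networks are built from declarative
    specifications and run on a small self-contained CPU engine, so the whole
    pipeline is exercisable without external datasets or accelerators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
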