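Package: cacseg
Title: Two-Stage Detection of Cervical Carotid Artery Calcifications in
    CBCT Slice Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and localizes cervical carotid artery calcifications
    (CAC) in cone-beam CT axial slice stacks with a two-stage pipeline:
    a per-slice classifier whose confidences are reduced to a single
    anatomical boundary (the C2-C3 disc level) by a least-squares step
    function fit, followed by patch-based semantic segmentation of
    calcification pixels with a class-weighted cross-entropy loss that
    compensates for the extreme foreground/background imbalance.  Because
    clinical CBCT data cannot be redistributed, the package ships a
    synthetic phantom generator with known boundary indices and lesion
    masks, making every stage trainable and testable end to end.  Includes
    patch extraction (random overlapping windows and fixed central
    windows), joint image/mask augmentation, probability-map reassembly,
    and the usual diagnostic metrics (sensitivity, specificity, PPV, NPV,
    accuracy, per-class and mean IoU).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
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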