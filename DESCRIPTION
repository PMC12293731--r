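Package: aaaquant
Title: Abdominal Aortic Aneurysm Quantification from Per-Slice Area Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream quantification of abdominal aortic aneurysms (AAA)
    from per-slice aortic cross-sectional area signals, i.e. the segmented
    pixel counts that an upstream segmentation/tracking stage emits for each
    axial CT slice. Provides screening for aneurysm presence from
    segmentation-failure patterns, aneurysm start/end boundary detection by a
    sliding-window expert rule and by a trainable bidirectional LSTM sequence
    labeler (implemented in C++ via RcppArmadillo), surrogate lumen volume and
    enlargement versus a linearly interpolated normal baseline, a synthetic
    cohort generator with known ground truth, and the full evaluation suite
    (interval Dice, R-squared, MAE, MSE, binary cross-entropy,
    confusion-matrix metrics) with patient-level cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tiff,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
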