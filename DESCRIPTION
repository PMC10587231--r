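Package: upalign
Title: Unsupervised Prediction Alignment for Classifier Recalibration
    Under Acquisition Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free recalibration of a binary classifier's output scores
    when the data acquisition pipeline changes (new scanner, new site, image
    processing update). The score distribution on the shifted domain is mapped
    onto a reference distribution by piecewise-linear cumulative-distribution
    matching, which preserves the rank order of predictions (and hence
    ROC-AUC) while restoring a pre-calibrated operating point such as the
    balanced sensitivity-equals-specificity threshold. Includes operating
    point selection and screening metrics (sensitivity, specificity, Youden's
    index, expected calibration error), a seeded synthetic score generator
    with monotone acquisition-shift warps, a streaming engine for weekly
    per-device recalibration with a running window, and a bootstrap evaluation
    protocol for new-site deployment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
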