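Package: restransnet
Title: Hybrid Residual-CNN/Transformer Classification of CT Lesion Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates ResTransNet, a hybrid residual convolutional
    and transformer network for binary classification of 128x128 grayscale CT
    lesion patches (developed for preoperative prediction of PD-1 expression
    status in hepatocellular carcinoma). Includes region-of-interest cropping
    and augmentation, patient-level hold-out splitting, a seeded synthetic
    CT-lesion cohort generator, three class-imbalance strategies (minority
    oversampling, class-distribution-reverse loss re-weighting, and a
    per-sample gradient penalty based on pairwise gradient cosine similarity),
    an SGD training loop with a step learning-rate schedule, classification
    metrics with ROC/AUC and decision-curve analysis, Kaplan-Meier and
    log-rank survival comparison of predicted groups, and feature-map /
    class-activation visualization. The network forward and backward passes
    are implemented in base R linear algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    pROC,
    survival,
    png,
    tiff,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
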