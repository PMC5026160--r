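Package: sniffsel
Title: Sparse Odor-Panel Selection and Diagnostic Accuracy for Parkinson Disease Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing forced-choice odor-identification tests
    (Sniffin' Sticks SS-16/SS-12) into minimal diagnostic panels for
    Parkinson disease. Implements L1-regularized logistic regression by
    cyclic coordinate descent over a regularization path to order odors by
    discriminative value, ROC analysis with DeLong confidence intervals,
    Youden-index cutoff selection, exact binomial (Clopper-Pearson)
    confidence intervals for diagnostic proportions, prevalence-adjusted
    predictive values, and rank-sum/chi-square group comparisons with
    Bonferroni adjustment. Includes a latent-trait simulator for
    four-alternative forced-choice item responses with a 25% guessing
    floor, calibrated to target sum-score moments, and an orchestrated
    discovery/validation study design with subset-size AUC sweeps and
    prospective evaluation in prodromal cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
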