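Package: extree
Title: Extracted Regression Trees for Black-Box Risk Model Distillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Distills any black-box tabular risk scorer into an interpretable
    CART-style tree: a diagonal-covariance Gaussian mixture is fitted to the
    training features by EM, synthetic feature vectors are sampled from it and
    labelled with the scorer's continuous risk scores, and a regression tree is
    fitted to the pairs (with a binarized decision-tree variant as the
    comparison arm). Ships a synthetic hospital-admission cohort generator with
    a known ground-truth readmission mechanism, cohort preparation (prior-visit
    counts, 30/90-day readmission labels, specialty filtering, one-hot
    encoding), reference logistic and feed-forward network scorers with a
    stratified k-fold rebalancing harness, imbalanced-classification metrics
    (AUC, average precision, MCC), and replicated 70-30 split evaluation with
    conservative chi-square-adjusted standard errors and significance flags.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
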