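Package: diafusion
Title: Fusion of Calibrated Classifiers for Diabetes Onset Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-source tabular data fusion and a posterior-probability
    classifier-fusion architecture for binary diabetes-onset prediction from
    eight routine clinical features. Provides Dempster-Shafer evidence
    combination utilities, mean-imputation and z-score preprocessing fit on
    training folds, an RBF-kernel support vector machine with Platt-type
    sigmoid calibration, a from-scratch single-hidden-layer backpropagation
    network, mean/min/max/product posterior combining rules with a tunable
    outlier threshold, stratified nested cross-validation with grid search,
    a confusion-matrix evaluation suite, and a seedable synthetic-data
    generator emulating multi-source clinical tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
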