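Package: agedelta
Title: Brain-Age Delta Modelling and Feature-Influence Analysis
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how feature selection shapes brain-age
    models and the downstream use of their deltas as disease biomarkers.
    Features in a subject-level table are ranked by k-nearest-neighbour
    mutual information with chronological age or with a pair of clinical
    labels; brain-age regression pipelines (linear, ridge, or support
    vector regression) are trained on healthy controls over nested feature
    sets with cross-validation and age-bias correction; the resulting
    deltas are evaluated as classifiers of clinical group pairs using
    stratified cross-validation with in-fold undersampling. Includes a
    synthetic aging-cohort generator with planted age and disease signal
    for fully reproducible experiments, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    pROC,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
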