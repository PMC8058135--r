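Package: connpred
Title: Predicting Behavioural Scores from Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for connectome-based prediction of behavioural
    scores from resting-state functional connectivity. Vectorizes symmetric
    parcel-by-parcel connectivity matrices into edge vectors, extracts
    latent features with unsupervised methods (PCA, ICA, dictionary
    learning, non-negative matrix factorization), predicts behavioural
    scores with elastic-net regression, tunes hyperparameters by
    leave-one-out and nested leave-one-out cross-validation, and
    back-projects regression coefficients into edge space to obtain
    predictive connectivity maps. Includes a synthetic cohort generator
    with known latent ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
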