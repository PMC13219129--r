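Package: rsnpfs
Title: Progression-Free Survival Prediction from Resting-State Network
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for predicting
    progression-free survival (PFS) in glioblastoma from preoperative
    resting-state network (RSN) functional connectivity. Implements
    within- and between-network similarity feature extraction with a
    ROI-mean imputation rule, minimum-redundancy maximum-relevance
    (MRMR) feature selection nested inside leave-one-out
    cross-validation, an augmentation-backed deep feed-forward
    regressor trained by L-BFGS with random restarts and a
    hyperparameter search, RANO-style progression classification with
    Kaplan-Meier, log-rank and Cox proportional-hazards analyses, and
    voxelwise map analyses including tumor frequency maps, point-biserial
    PFS association maps, per-network Cliff's delta effect sizes and
    feature-weight projection. A synthetic-cohort generator with planted
    network covariance and outcome signal makes the full pipeline
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
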