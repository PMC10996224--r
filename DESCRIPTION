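Package: dcisnet
Title: Multi-Task U-Net for Mammographic Calcification Segmentation and
    DCIS Risk Classification
Version: 0.1.0
Authors@R:
    person("dcisnet", "developers", role = c("aut", "cre"),
           email = "dcisnet@example.org")
Description: A fully convolutional encoder-decoder network that jointly
    segments mammographic microcalcifications and classifies lesions as
    low-risk (grade I/II) versus high-risk (grade III and/or occult
    invasive) ductal carcinoma in situ (DCIS). Includes a synthetic
    mammogram phantom generator with grade-dependent calcification
    morphology, DICOM/PNG/TIFF/NRRD image input, the training-time
    augmentation pipeline (vendor lookup tables, unit rescaling, lesion
    centred crops, flips, gamma, additive noise), patient-level
    grade-stratified train/test splitting with k-fold partitioning, a
    focal classification loss combined with a top-k pixel cross-entropy
    segmentation loss, an Adam training loop with a step learning-rate
    schedule, and DICE/AUROC/PPV/NPV evaluation with per-patient
    multi-view probability averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
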