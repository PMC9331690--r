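Package: strokefeat
Title: Feature-Set Comparison for Functional Outcome Prediction After
    Ischemic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully synthetic re-implementation of a
    follow-up DWI analysis pipeline for acute ischemic stroke: a seeded
    generator of DWI-like volumes with planted lesion-volume and
    intensity-heterogeneity signal, white-stripe intensity
    normalization and resampling, a threshold lesion segmenter, a
    pinned 100-feature 3D radiomics catalog (first-order, shape, GLCM,
    GLRLM, GLSZM, GLDM), a 3D convolutional autoencoder whose
    100-dimensional latent space serves as a learned feature set, SVM
    classifiers with robust scaling and grid search, and evaluation
    statistics (Mann-Whitney AUC, DeLong's paired test, Kernel SHAP
    attributions) implemented from first principles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
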