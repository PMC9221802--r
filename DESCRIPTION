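Package: rtae
Title: Radiomics Models for Predicting HCC Response to Transarterial Embolization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements two radiomics modelling workflows for predicting the
    response of hepatocellular carcinoma (HCC) to transarterial embolization
    from per-phase MRI feature tables: an elastic-net-penalized logistic
    selection step followed by a ridge-penalized logistic refit on an 80/20
    split, and a hybrid descriptive-inferential pipeline that ranks features
    by point-biserial correlation, retains them through an iterative
    add-one-feature logistic-regression stopping rule, and classifies with
    linear discriminant analysis under stratified disjoint 5-fold
    cross-validation. Also provides mRECIST tumor-response classification,
    cohort group-comparison statistics (Fisher exact, Pearson chi-squared,
    Mann-Whitney U), ROC/AUC evaluation with DeLong confidence intervals, a
    bounded IBSI-style radiomics feature extractor (first-order, GLCM, shape,
    single-level 3D Haar wavelet) for image+mask volumes, and a synthetic
    cohort generator with planted effects that replaces the unavailable
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    RNifti,
    stats,
    utils
Suggests:
    jsonlite,
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
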