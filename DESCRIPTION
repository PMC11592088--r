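Package: usradiomics
Title: Ultrasound Radiomics Pipeline for Benign/Malignant Nodule Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reproducible ultrasound-radiomics workflow for
    discriminating benign from malignant thyroid nodules: synthetic B-mode
    nodule cohort generation, ROI preprocessing (isotropic resampling with
    pixel caps, fixed-bin-number discretization), a filtered-image bank
    (gradient, Laplacian-of-Gaussian, square, square-root), IBSI-style
    intensity and texture feature families (intensity statistics, intensity
    histogram, GLCM, GLRLM, GLSZM, NGTDM, NGLDM), variance and
    mutual-information feature screening, ADASYN minority oversampling,
    three majority-vote ensemble classifiers (random forest, PCA+FDR SVM,
    PCA+FDR kNN) under nested 4-fold cross-validation, and the associated
    metric and nonparametric statistical reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    tiff,
    jsonlite,
    igraph,
    ranger,
    e1071,
    class,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
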