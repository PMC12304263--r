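Package: plasmavib
Title: Dual-Modality Vibrational Spectroscopy Diagnostics for Blood Plasma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for ATR-FTIR and Raman spectroscopy of
    blood plasma aimed at endometrial-cancer detection. Provides spectral I/O
    and validation, asymmetric-least-squares and rubber-band baseline
    correction, vector and CH2-band normalisation, low-level fusion of the two
    modalities by spectral concatenation, repeated patient-level 70/30
    train/test evaluation with PCA dimensionality reduction and four
    classifiers (SVM, random forest, k-nearest neighbours, logistic
    regression), Random-Forest wavenumber ranking with region-of-interest
    binning and per-wavenumber ANOVA, group-level statistics (MANOVA on PCA
    scores, t-tests from summary statistics, Pearson chi-squared), and a
    synthetic plasma-spectrum generator that emulates the statistical
    structure of wet and dried plasma acquisitions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    randomForest,
    e1071,
    class,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
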