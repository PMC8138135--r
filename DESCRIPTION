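Package: gaitdep
Title: Gait-Based Depression Recognition from Skeleton Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for recognizing depression from
    Kinect-style 25-joint skeleton walking recordings. Provides a plain-text
    recording format, a synthetic gait cohort generator with configurable
    case/control kinematics, preprocessing (spine-relative coordinates,
    walking-pass segmentation, left-toe toe-off gait-cycle detection,
    five-point Gaussian low-pass filtering), three feature banks
    (10 spatiotemporal, 300 time-domain, 825 DFT frequency-domain features),
    a logistic-regression variance analysis (PCA at 95 percent cumulative
    variance, stepwise forward selection, odds ratios, Nagelkerke pseudo
    R-squared), and linear-SVM classification with sequential backward
    selection and stratified 10-fold cross-validation reporting
    sensitivity, specificity and AUC for all feature-block combinations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC,
    withr
Config/testthat/edition: 3
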