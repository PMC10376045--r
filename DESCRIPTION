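Package: decelfbp
Title: Predicting Minimum Fetal Blood Pressure from Heart-Rate Decelerations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the relationship between fetal heart rate
    (FHR) decelerations and the minimum fetal blood pressure (FBP) reached
    during umbilical-cord occlusions. Provides a seeded simulator of
    repeated-occlusion experiments in near-term fetal sheep and of
    human-style cardiotocography traces, percentile-based labelling of
    occlusions with their minimum FBP, time-offset augmentation and
    normalisation of 150 s FHR segments, a 1-D convolutional network
    regressor trained with a mean-absolute-percentage-error loss, a
    leave-one-animal-out evaluation protocol, and application of trained
    models to human FHR traces with outcome-group comparison and trend
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
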