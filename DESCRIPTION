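Package: gaitfog
Title: Knee-Worn Accelerometer Gait Parameters and Freezing-of-Gait Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates spatiotemporal gait parameters from a knee-worn triaxial
    accelerometer and screens for freezing of gait (FoG) in Parkinson's disease.
    Initial contacts (heel strikes) are detected from the low-pass filtered,
    orientation-corrected vertical acceleration via integration smoothing and a
    Gaussian continuous-wavelet-transform derivative; step time, stride time,
    step length, stride length and walking speed follow from an extended
    inverted-pendulum model in which the per-step vertical excursion of the
    sensor is obtained by double integration. A 14-feature gait descriptor
    (the five spatiotemporal parameters, per-axis standard deviations,
    zero-lag cross-axis correlations and per-axis harmonic ratios) is augmented
    with all 14 principal-component scores into a 28-dimensional vector and fed
    to four classifiers (RBF support vector machine, k-nearest neighbours,
    decision tree, Gaussian naive Bayes) under a stratified 70:30
    train-validation protocol repeated over seeded simulations. Concurrent
    validity against a reference system is summarised by per-subject mean
    error rates and Pearson correlations. A ground-truthed synthetic walk and
    cohort generator supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    pracma,
    purrr,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
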