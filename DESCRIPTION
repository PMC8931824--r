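Package: facestyle
Title: Decision-Making Style Recognition from 3D Facial Landmark Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline that maps 3D facial-landmark time series
    (1347 points sampled at 30 Hz) to predicted scores on the five
    dimensions of the General Decision-Making Style questionnaire
    (spontaneous, avoidant, rational, dependent, intuition).  Implements
    face-local coordinate shifting, mean filtering, frame trimming,
    variance-based landmark screening, sliding-window FFT modulus
    features, PCA dimensionality reduction, four linear regression
    variants (OLS, linear-kernel SVR, GCV-tuned ridge, Bayesian ridge),
    stratified train/validation splitting, 10-fold cross-validation,
    and odd/even-frame split-half reliability.  Ships a synthetic-cohort
    generator with a planted, recoverable trait-to-motion spectral
    coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    e1071,
    generics,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
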