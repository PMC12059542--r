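Package: histocal
Title: Bubble-Cloud Localization and Robot Calibration for CBCT-Guided
    Histotripsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated localization of histotripsy bubble-cloud treatment
    zones from pre- and post-treatment cone-beam CT volumes of a layered
    agar phantom, and estimation of the 3D offset between the planned
    (robot) focal point and the actual cavitation location.  Implements
    rigid mean-squared-error registration, Gaussian-filtered difference
    imaging, Nelder-Mead region-of-interest optimization with a dual-rule
    Z localizer, a four-cloud joint calibration estimator, the associated
    accuracy metrics (mean residual error, mean absolute deviation), and a
    synthetic layered-phantom scanner so the full calibration workflow can
    be exercised and validated without access to a C-arm.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
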