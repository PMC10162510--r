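Package: wantpower
Title: Predict Wingate Anaerobic Power Outputs from Graded Exercise Test Variables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives candidate predictors from incremental treadmill exercise
    test trajectories at 85, 90 and 100 percent of age-predicted maximal heart
    rate, trains greedy forward-selection multiple linear regression models of
    Wingate anaerobic peak and mean power with stratified calibration/test/
    validation splits and resampled percent-error estimation, applies a set of
    previously published prediction equations, and simulates synthetic cohorts
    with planted linear outcome models for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
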