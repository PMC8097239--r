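Package: openinterval
Title: Open Birth Interval Distributions from Demographic Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tabulates the distribution of married women by open birth
    interval (time since the most recent live birth) from DHS-style survey
    microdata, decomposes it by age and parity, fits a two-parameter power
    curve and three comparator models, and relates the fitted parameters to
    total fertility, general fertility, and children ever born across a
    cross-country panel. Includes a monthly-step reproductive-history
    microsimulator for generating survey-style cohorts under configurable
    fertility regimes, and stationary renewal-theory routines linking closed
    birth-interval distributions to the open-interval (backward recurrence
    time) distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
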