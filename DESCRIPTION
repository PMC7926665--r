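Package: mobilexpo
Title: Mobility-Based Assessment of Long-Term Ambient PM2.5 Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how accounting for individual mobility changes
    long-term ambient PM2.5 exposure estimates, and how that change is
    moderated by routine travel patterns and by the spatial exposure model.
    Includes a synthetic-data generator for daily pollution fields (Gaussian
    random fields with exponential covariance), sparse station networks, and
    agent trajectories with known ground truth; daily travel-pattern metrics
    (radius of gyration, non-home time) and cohort stratification;
    single-sourced ordinary-kriging and multi-sourced regression-kriging
    concentration surfaces with spatial k-fold cross-validation; residence-
    and mobility-based time-weighted exposure aggregation; and random-intercept
    interaction models comparing the two approaches across travel-pattern
    strata and surface types.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
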