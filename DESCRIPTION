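Package: catchcurve
Title: Catch-Curve Estimation of Total Mortality Across Fishery Management Regimes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Length-converted catch-curve analysis for data-poor benthic
    fisheries. Converts shell-length records to ages with the von Bertalanffy
    growth model, builds age-frequency distributions on 0.2-year classes,
    estimates total instantaneous mortality (Z) from the descending limb by
    log-linear regression with spline-located full-recruitment age and
    zero-gap right truncation, and compares Z across management regimes,
    sites, management areas and years by ANCOVA on the limb data with
    post-hoc slope contrasts. Includes a fishing-mortality decomposition
    against a no-take natural-mortality reference, frequency-matched
    subsampling for unbalanced strata, a bootstrap minimum-sample-size
    diagnostic, and an equilibrium age-structured cohort simulator with
    logistic selectivity for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    car,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
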