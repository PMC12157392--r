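Package: codevelop
Title: Longitudinal Brain-Cognition Co-Development Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how functional brain connectomes and cognition
    co-develop across two longitudinal timepoints. Provides seeded synthetic
    multi-site cohort generation with planted brain-cognition couplings,
    functional-connectivity construction from censored multi-run time series,
    longitudinal ComBat-style site harmonization, stability and change
    statistics (mixed models, change scores, transferred-loading PC1),
    test-retest reliability algebra including scan-duration extrapolation and
    change-score reliability, site-cluster nested kernel ridge regression with
    Haufe-transform predictive network features, permutation and spin-test
    inference, and network-block convergence/divergence classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
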