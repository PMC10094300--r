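Package: greenmob
Title: Effect-Heterogeneity Analysis of Green-Space Exposures via Weighted
    Model-Based Recursive Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering subgroups with heterogeneous
    exposure-outcome associations in observational cohort studies of
    residential green space and self-rated health. Implements stabilized
    inverse-probability weighting for binary exposures (propensity scores via
    logistic regression) and continuous exposures (generalized propensity
    scores via kernel density estimation), covariate-balance and positivity
    diagnostics, model-based recursive partitioning of weighted binary
    logistic exposure-outcome models with score-based parameter-instability
    tests (supLM for numeric moderators, chi-square for categorical ones),
    per-node effect inference (odds ratios with sandwich standard errors,
    bootstrap risk differences) and a heterogeneity-versus-prevalence
    classification of splits. A seeded synthetic-cohort generator with
    planted subgroup structure supports calibration and recovery testing
    without access to restricted cohort data.
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
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
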