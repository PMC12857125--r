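Package: maihda
Title: Bayesian Multilevel Analysis of Individual Heterogeneity and
    Discriminatory Accuracy for Intersectional Strata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits two-level Bayesian random-intercept models (logistic for
    binary outcomes, linear for log-transformed skewed outcomes) with
    individuals nested in intersectional social strata, the model family known
    as MAIHDA (Multilevel Analysis of Individual Heterogeneity and
    Discriminatory Accuracy).  Provides construction of crossed
    sex x race/ethnicity x age x education strata, configurable exclusion
    filters, shrunken per-stratum predictions decomposed into additive and
    interaction components with credible intervals, latent-response variance
    partition coefficients and proportional change in variance, log-normal
    back-transformation of skewed consumption outcomes, ranked-strata tables,
    caterpillar plots, between-outcome correlation with outlier flagging, and
    a synthetic survey-cohort generator for known-truth parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
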