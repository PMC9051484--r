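Package: twinpath
Title: Longitudinal Twin Variance-Component Models for Age-Anchored Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com", role = c("aut", "cre"))
Description: Tools for biometrical genetic analysis of longitudinal twin data,
    motivated by twin studies of MRI-predicted brain age. Provides a synthetic
    twin-cohort generator, age-interval anchoring and covariate residualization
    of irregularly timed assessments, zygosity-specific twin-pair and polyserial
    correlations, a raw-data full-information maximum likelihood (FIML) engine
    for twin-pair multivariate normal models with missing entries, a zoo of
    competing multivariate genetic models (correlated factors / Cholesky,
    autoregressive simplex, common pathway, independent pathway), likelihood
    ratio tests, AIC, profile-likelihood confidence intervals, and an
    end-to-end model-selection pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
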