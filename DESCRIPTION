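Package: zicmpreg
Title: Conway-Maxwell-Poisson and Zero-Inflated Count Regression for
    Underdispersed Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting of Poisson, Conway-Maxwell-Poisson
    (CMP), zero-inflated Poisson (ZIP) and zero-inflated CMP (ZICMP)
    regression models for count outcomes that are underdispersed, zero
    inflated, or both, such as deaths per road traffic accident.  Provides
    exact series evaluation of the CMP normalizing constant, probability
    mass functions and moments (exact and asymptotic-approximation forms),
    reproducible samplers, likelihood-ratio and score tests for dispersion
    and zero inflation, generalized Pearson goodness-of-fit statistics,
    Cramer's V covariate screening, a synthetic accident-data generator
    with parameter-recovery experiments, and delimited-text input/output
    with Table-style model-comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
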