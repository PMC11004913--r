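Package: ocscreen
Title: Longitudinal Multimarker Screening Models for Early Ovarian Cancer Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint multivariable Bayesian change-point modelling and per-marker
    LSTM classification of longitudinal serum biomarker series (CA125, HE4,
    glycodelin) for early ovarian-cancer detection. Provides a synthetic-cohort
    generator matching the hierarchical generative model, an MCMC sampler
    (Gibbs, Metropolis-Hastings and reversible-jump steps) with Gelman-Rubin
    diagnostics, posterior-predictive risk scoring with a population prevalence
    prior, a from-scratch LSTM sequence classifier with channel-wise hidden
    states and nested cross-validated tuning, and a shared evaluation layer
    (stratified repeated cross-validation, AUC, sensitivity at fixed
    specificity, paired permutation tests, screening horizons and lead-time
    statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
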