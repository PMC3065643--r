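Package: dualRR
Title: Dual-Sample Randomized-Response Models for Prevalence and Cheating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint estimation of the prevalence of sensitive behaviour and of
    self-protective "no" answering (cheating) from dual-sample surveys in
    which the same binary questions are asked under a randomized-response
    design in one sample and by direct questioning in the other. Provides
    construction and validation of randomized-response misclassification
    matrices (forced-response and forced-yes designs, Kronecker profile
    designs), a log-linear parameterization of the latent answer-profile
    distribution, a finite mixture model with a degenerate cheating
    component and logistic cheating regressions, maximum-likelihood fitting
    with BIC model comparison and Wald screening, Bayesian inference by
    data-augmentation Metropolis-within-Gibbs sampling with Geweke
    convergence checking and prior-sensitivity analysis, posterior
    predictive goodness-of-fit checking, pairwise-question sensitivity
    analysis, and a survey simulator for calibration and parameter-recovery
    studies. The Clark-Desharnais two-sample cheating model is included as
    a restricted special case.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
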