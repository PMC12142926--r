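Package: injurybayes
Title: Bayesian Hierarchical Models for Sport Injury Surveillance Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling injury counts from stratified sport injury
    surveillance tables with athlete-exposure denominators. Provides four
    count-regression families (Poisson, Poisson with school random effects,
    negative binomial, and zero-inflated negative binomial, all with
    log-exposure offsets), fitted by an adaptive Hamiltonian Monte Carlo
    sampler with rank-normalized split R-hat and bulk effective-sample-size
    convergence diagnostics. Includes a closed-form Gamma-Poisson conjugate
    rate posterior with prior-sensitivity analysis, a four-part posterior
    predictive check suite (maxima exceedance, zero proportions, actual
    versus predicted rates, randomized probability integral transforms),
    Pareto-smoothed importance-sampling leave-one-out cross-validation for
    model comparison, posterior summary tables with rate-ratio
    interpretation, a frequentist negative binomial comparator, and a
    synthetic surveillance-data generator with recorded ground truth for
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    glmmTMB,
    ggplot2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
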