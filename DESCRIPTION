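Package: sohga
Title: Hybrid Genetic Algorithm Model Selection for Population
    Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A self-contained toolkit for automated population
    pharmacokinetic model selection.  Provides closed-form linear
    compartment models, a nonlinear mixed-effects estimator (first-order
    and first-order conditional with interaction approximations of the
    marginal likelihood) with empirical Bayes estimates and a covariance
    step, a binary-genome single-objective hybrid genetic algorithm with
    parsimony and diagnostic penalties, niching, elitism and a one-bit
    downhill local search, an automated stepwise covariate modeling
    comparator, a correlated-covariate simulation study generator, and
    model comparison metrics (AIC, BIC, MPE, RMSE, Cohen's kappa).
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
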