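Package: diptrial
Title: Decreasingly Informative Priors for Single-Arm Phase II Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and evaluation of single-arm Bayesian phase II clinical
    trials monitored continuously after every enrolled subject. Implements
    decreasingly informative priors (DIP), whose effective prior sample size
    equals the unobserved sample size N - n and therefore shrinks to
    non-informative as accrual completes, for Bernoulli, Poisson and
    Gaussian (known variance) outcomes, alongside the standard
    non-informative and Thall-Simon informative comparators. Provides
    conjugate posterior updates, posterior-probability efficacy and futility
    stopping rules, Monte Carlo and exact (dynamic-programming) operating
    characteristics, stopping-boundary tables, and a grid search for the
    smallest planned sample size giving an admissible design (power at
    least 80 percent, type I error at most 5 percent).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
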