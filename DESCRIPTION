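Package: sdmem
Title: Stochastic Differential Mixed-Effects Models via Extended Kalman
    Filtering and FOCE/FOCEI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation for nonlinear mixed-effects models
    whose within-subject dynamics are stochastic differential equations
    (SDMEMs). A continuous-discrete extended Kalman filter computes one-step
    prediction errors and output covariances for each subject; the population
    likelihood is approximated by the Laplace method around the posterior mode
    of the random effects, using first-order conditional estimation with or
    without interaction (FOCEI/FOCE); gradients are obtained from forward
    sensitivity propagation rather than finite differences of the objective;
    and nested BFGS optimization recovers fixed effects, the random-effects
    covariance factor, measurement-error and system-noise parameters. Includes
    a one-compartment pharmacokinetic model with first-order absorption and
    Michaelis-Menten elimination, a nicotinic-acid disposition model with
    endogenous synthesis, an Euler-Maruyama simulator for generating synthetic
    populations, a fixed-interval smoother for individual fits with
    uncertainty bands, and a replicate simulation-study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
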