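Package: persbo
Title: Personalized Bayesian Optimization of Neurostimulation Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for adaptive, personalized selection of transcranial
    alternating current stimulation (tACS) parameters via Bayesian
    optimization. Implements a Gaussian-process surrogate with a product
    covariance over stimulation coordinates (frequency, current) and a
    per-subject baseline-ability covariate, expected-improvement and GP-UCB
    acquisition over the discrete hardware lattice, EZ-diffusion drift-rate
    scoring of trial-level accuracy and response times, the sequential
    double-blind burn-in/optimization protocol, a noisy Hartmann-3D
    benchmark comparing personalized BO against standard BO and random
    search, and a synthetic-cohort generator for end-to-end testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
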