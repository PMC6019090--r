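Package: treedisturb
Title: Bayesian Hump-Shaped Growth Models for Trees Under Chronic Disturbance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a hump-shaped, size-dependent model of tree diameter growth
    in which the maximum growth rate depends on chronic anthropogenic
    disturbance (pruning, debarking) and on intraspecific functional traits
    (wood density, leaf mass per area). Provides adaptive
    Metropolis-within-Gibbs MCMC inference with convergence diagnostics,
    forward selection of trait-by-disturbance interaction terms by WAIC,
    derived quantities such as the pruning-cost surface and the zero-cost
    wood-density threshold, trait computation from raw core and leaf
    measurements, and a seeded synthetic-inventory generator for simulation
    studies of parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
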