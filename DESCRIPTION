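Package: fkibm
Title: Discrete-Time Individual-Based Simulation of Logistic Growth and
    Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates population dynamics with a discrete-time,
    synchronous individual-based model in which every individual
    independently decides on birth, death and movement at each time step.
    Provides lattice substrates (one-dimensional chain, rectangular
    4-neighbour and hexagonal 6-neighbour grids) with habitability masks,
    a random-walk movement term with microscopic and variance-slope
    diffusion-coefficient estimators, a density-dependent stochastic
    birth-death growth term with its exact transition kernel and master
    equation, and the combined growth-diffusion simulator that approaches
    the Fisher-Kolmogorov equation in the continuum limit.  Analytic
    layers give the effective carrying capacity of the stochastic
    logistic model, the dispersion relation of the discrete update and
    the finite-population correction to the front speed.  Experiment
    drivers regenerate the diffusion, growth and front-speed summary
    tables and a masked-corridor arrival-time demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
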