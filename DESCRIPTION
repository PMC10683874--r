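Package: mapbmi
Title: Closed-Loop Simulation and Analysis of a Hippocampal Map-Based
    Brain-Machine Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a hippocampal place-cell population, goal-directed
    running behaviour and theta-band local field potentials in a square
    virtual arena; trains an augmentation-robust neural-network position
    decoder with a Poisson Bayesian maximum-a-posteriori baseline; runs
    closed-loop brain-machine-interface navigation ("Jumper") and object
    location control ("Jedi") tasks driven by a parameterized intention
    agent; and implements the accompanying statistics: unit-identity and
    goal-location shuffle nulls, angle-to-goal circular histograms,
    population-vector versus reference-population-vector correlation
    profiles, population burst event detection and excision, and
    movement/immobility theta spectral analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
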