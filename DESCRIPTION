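Package: photomotion
Title: Four-State Photoswitch Kinetics, Markov Transition Analysis and
    Motion Propensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the photochemistry of molecular photoswitches
    with four thermally stable diastereomeric states. Provides a forward
    photokinetic model with composition-dependent photon partitioning,
    global estimation of row-stochastic Markov transition matrices from
    mole-fraction time courses, per-channel photoisomerization quantum-yield
    determination, partitioning of photoreactions into single-bond-rotation,
    double-bond-isomerization and hula-twist motions, reversible first-order
    thermal kinetics with Eyring barrier and half-life conversion,
    isosbestic-point and rank diagnostics for absorption-spectra series, and
    a seeded synthetic-data generator emulating NMR composition time courses,
    thermal decays and matrix-irradiation spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
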