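Package: mcfrise
Title: Pressure-Balance Modelling of Capillary Rise in Straight and Looped
    Microcapillary Films
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models, simulates and analyses capillary rise of water, plasma
    and whole blood in melt-extruded microcapillary film test strips used for
    dip-and-test haemostasis assays. Implements a Lucas-Washburn-type
    pressure-balance model for straight and looped strips (loops add
    frictional path length without changing the equilibrium height), surface
    parameter estimation from equilibrium heights, finite-difference velocity
    profiling with reciprocal-height analysis windows, viscosity fitting,
    replicate-group statistics (one-way ANOVA with Tukey HSD), a seeded
    synthetic-data generator for ten-capillary strips, and a reproducible
    simulate/analyze/report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
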