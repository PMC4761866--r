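Package: magplume
Title: Dual-Cue Island Navigation: Geomagnetic Isoline Drift and Odor-Plume Dispersal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the sequential magnetic-then-chemical homing strategy hypothesized
    for island-nesting sea turtles. Evaluates the main geomagnetic field anywhere on the
    globe by spherical-harmonic synthesis from epoch-tabulated Gauss coefficients,
    extracts constant-intensity isolines and quantifies their secular drift, advects
    waterborne and airborne odorant particles through gridded velocity fields with
    fourth-order Runge-Kutta time stepping and stochastic horizontal dispersion,
    scores plume-isoline intersection frequencies with binomial confidence intervals,
    and runs an agent-based simulation comparing isoline-following, plume-following,
    and dual-cue navigation strategies. Ships synthetic ocean, wind, and magnetic
    field generators with known ground truth so the full pipeline is testable without
    external hindcast data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ncdf4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
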