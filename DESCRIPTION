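Package: antsearch
Title: Centred-Loop Systematic Search Simulator for Desert Ants
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the looping "systematic search" of desert ants
    (Cataglyphis) around a presumed nest site using a home-vector model:
    deterministic centred-loop dynamics governed by an incremental turning
    angle, a step length and a backward factor, with transient Gaussian
    block perturbations mimicking unsystematic path-integration error.
    Provides both the production Cartesian integrator and an exact polar
    oracle, continuous within-run parameter schedules, trajectory analytics
    (moving-average smoothing, distance-to-origin series, loop segmentation
    and loop-size statistics), published parameter presets, CSV/config I/O,
    plotting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
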