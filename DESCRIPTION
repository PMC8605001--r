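Package: thermoskin
Title: Hyperbolic Bioheat and Thermoelastic Vibration of Laser-Heated Skin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the coupled two-dimensional hyperbolic (Cattaneo-Vernotte)
    bioheat equation and the thermoelastic vibration of skin tissue under a laser
    heating source. The coupled axisymmetric partial differential equations are
    reduced to a three degree-of-freedom ordinary differential equation system by
    a Galerkin weighted-residual projection onto Bessel and Gaussian shape
    functions, with heuristic elimination of the free-surface traction
    conditions. Includes six laser time-profile families (single pulse,
    repetitive pulse, repeating sequence stairs, step, repetitive ramp,
    harmonic), field reconstruction and summary metrics, an independent
    axisymmetric finite-difference solver for the uncoupled hyperbolic bioheat
    equation used for verification, and a scenario runner with presets.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
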