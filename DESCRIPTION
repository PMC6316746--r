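Package: bioheat2d
Title: Bioheat Simulation and Chart-Based Tumor Size Estimation on a 2D
    Breast Phantom
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Finite-volume solver for the steady-state and transient Pennes
    bioheat equation on a semicircular two-dimensional breast phantom with an
    embedded circular tumor, a Dirichlet core condition on the flat base and
    a nonlinear convective-radiative condition on the curved skin surface.
    Reduces solved temperature fields to the diagnostic surface temperature
    difference (maximum minus minimum along the skin arc), sweeps the forward
    model into estimation charts, packages published reference charts for
    three tumor positions, and inverts an observed surface temperature
    difference into a tumor-size estimate by nearest-match chart lookup.
    Includes closed-form conduction oracles, an energy-balance audit, and a
    YAML-configured command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
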