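Package: lumenchain
Title: Hydro-Osmotic Coarsening Dynamics of Lumen Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for the collective dynamics of pressurized biological
    cavities (lumens) coupled by screened hydraulic and diffusive fluxes
    through intercellular bridges. Implements the coupled osmotic-hydraulic
    ordinary differential equations for one-dimensional chains of
    two-dimensional lumens with active ion pumping, an analytic solver for
    the screened Poiseuille-diffusion bridge profiles, an adaptive
    Runge-Kutta-Fehlberg integrator with detection and handling of
    topological events (lumen collapse and coalescence), a hydraulic-chain
    mean-field reference dynamics, and the ensemble observables (log-binned
    lumen counts, power-law exponent fits, rescaled size distributions,
    final-lumen position distributions) needed to study coarsening scaling
    laws and pumping-driven symmetry breaking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
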