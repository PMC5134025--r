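Package: thromboflow
Title: Haemodynamics-Based Simulation of Thrombus Formation in Dissected Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional pulsatile computational haemodynamics toolkit for
    predicting shear-driven thrombus formation and growth in idealized aortic
    dissection and backward-facing-step geometries. Couples an incompressible
    fractional-step flow solver with Quemada blood rheology to
    convection-diffusion-reaction transport of residence time, platelets and a
    lumped coagulant species. Thrombus is tracked as a bound-platelet field
    gated by time-averaged wall shear stress and cycle-averaged bulk shear
    rate, and feeds back on the flow through a porous-medium momentum sink and
    clot porosity. Includes a Lagrangian particle tracer with the
    Grigioni-Nobili platelet activation state (PAS) index, analytic
    verification benchmarks (Poiseuille, Womersley), legacy-VTK and CSV
    output, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
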