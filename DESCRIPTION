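Package: aneuflow
Title: Pulsatile Non-Newtonian Hemodynamics of Coiled Sidewall Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics of idealized sidewall
    cerebral aneurysms. Generates parametric 2D aneurysm geometries on a
    Cartesian grid, solves transient incompressible laminar flow of
    hematocrit-dependent Casson blood with a fractional-step projection
    method on a staggered (MAC) grid, models endovascular coil packing as an
    isotropic porous medium with a Kozeny-Carman Darcy momentum sink, and
    drives a face-centered central-composite design / response-surface
    campaign over coiling porosity, hematocrit, sac section area and parent
    vessel radius to quantify their effects on sac-wall pressure, intrasac
    velocity, wall shear stress and the oscillatory shear index.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
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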