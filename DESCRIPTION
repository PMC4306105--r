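Package: stentflow
Title: Hemodynamics and Drug Transport in Stented Curved Arteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Finite-volume simulation of steady laminar blood flow and
    drug elution for a drug-eluting stent deployed in a curved artery.
    Builds a structured curvilinear mesh of the bend-plane channel with
    square stent struts, solves the incompressible Navier-Stokes
    equations with a SIMPLEC pressure-velocity coupling, solves the
    conjugate advection-diffusion drug-transport problem across the
    lumen/vessel-wall interface, and computes the derived quantities of
    interest in stent design: wall shear stress profiles, low-WSS area
    fractions, Dean numbers and the secondary (Dean-vortex) flow on the
    circular cross-section, and drug-concentration line profiles and
    segment statistics. A Reynolds-sweep driver reproduces the standard
    four-case study (Re 200-800) with CSV/VTK/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
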