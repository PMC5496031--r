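Package: retchol
Title: Compartmental Modelling of Cholesterol Turnover, Delivery and Drusen
    Dynamics in the Outer Retina
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A steady-state and time-dependent simulator of cholesterol fluxes
    in the outer retina. Implements a ten-compartment transit-chain model of
    disc cholesterol in the rod outer segment with a recyclable pool, the
    coupling of LDL transcytosis across the choriocapillaris endothelium with
    Michaelis-Menten LDL-receptor uptake by the retinal pigment epithelium,
    ABCA1-mediated and ApoB-particle cholesterol efflux into Bruch's membrane,
    linear drusen growth and macrophage-mediated drusen clearance, and a
    hindered-diffusion (Renkin/Stokes-Einstein) calculator for particle
    permeation through diaphragmed fenestrae. Ships a versioned parameter
    registry with percent uncertainties and provenance, scenario tables for
    the model's figures, and lognormal Monte-Carlo uncertainty propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
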