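Package: fracbioheat
Title: Time-Fractional Pennes Bioheat Modelling for Nanoparticle-Assisted
    Hyperthermia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves the time-fractional (Caputo) Pennes bioheat equation for
    nanoparticle-assisted hyperthermia of perfused tissue in a porous medium
    with Rosseland thermal radiation.  The dimensionless model is solved two
    independent ways: a closed-form Laplace-domain solution inverted
    numerically with Durbin's Fourier-series method or Zakian's rational
    approximation, and an implicit Caputo L1 finite-difference scheme that
    serves as a cross-validation oracle.  Includes a thermophysical property
    database for blood and common nanoparticle species, Hamilton-Crosser
    effective-conductivity correlations with particle shape factors, wall
    Nusselt numbers and heat-transfer-enhancement tables, parameter sweeps,
    and a YAML/JSON-configured command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
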