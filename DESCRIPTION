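Package: wallsense
Title: Minimal Biophysical Models of Plant Cell Wall Mechanosensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates minimal one-dimensional biophysical models of
    mechanosensing at the plant cell wall. The cell wall is a
    viscoelastoplastic (Lockhart/Ortega) element with elastic modulus K_w,
    viscosity eta_w and yield threshold Y. Two sensor classes are modelled:
    a sensor associated with a minor load-bearing structure (a Maxwell
    branch of stiffness K_s and viscosity eta_s in parallel with the wall)
    and a sensor bound to a major load-bearing structure (a soft spring
    stretched by wall expansion that dissociates with a force-dependent,
    Bell-type hazard). The package builds stress and strain-rate input
    waveforms, solves the sensor-force dynamics, solves the age-structured
    renewal population of bound sensors, runs matched stochastic single-bond
    ensembles, classifies sensing regimes, and ships scenario presets that
    reproduce the qualitative response signatures of the two sensor classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
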