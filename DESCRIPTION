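Package: cryodorm
Title: Active and Dormant Microbial Biomass Dynamics on Glacier Surfaces
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Process-based model of heterotrophic microbial biomass on
    glacier surfaces, split into active and dormant pools coupled to
    dissolved organic carbon. State switching between the pools is driven
    by a sigmoidal (Fermi-Dirac form) function of temperature; growth
    follows Michaelis-Menten kinetics on DOC, with first-order mortality
    and per-biomass maintenance costs for both pools. Ships three
    idealized freeze/thaw scenario presets, an ODE integrator with
    segment-wise restarts for discontinuous forcing, trajectory summaries
    (active fraction, biomass change, catabolism partition), and a
    statistics module for BONCAT-style active-fraction cell counts:
    per-field active fractions, grouped summaries, one-way ANOVA, and a
    beta-binomial synthetic count generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
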