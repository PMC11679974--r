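Package: dipot
Title: Lipid Monolayer Electrostatics: Areas per Lipid, Dipole Potentials and
    Gouy-Chapman Corrections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of Langmuir monolayer experiments at the air-water
    interface: extraction of the saturation point from surface-pressure versus
    amount-of-lipid isotherms by two-line interception, polynomial description
    of pi-area isotherms and interpolation of the area per lipid at a chosen
    lateral pressure, Helmholtz parallel-plate estimation of transverse dipole
    moments and dipole potentials, Gouy-Chapman (Grahame equation) correction
    of measured interfacial potentials for charged monolayers, additivity and
    replacement predictions for lipid mixtures, and transbilayer dipole
    potentials for asymmetric leaflet compositions. Includes seeded synthetic
    generators with recorded ground truth so that every pipeline stage can be
    validated without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
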