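Package: crumplefet
Title: Electric Double Layer Screening and Dose-Response Analysis for
    Deformed-Graphene FET Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for field-effect-transistor (FET) nucleic-acid
    biosensors built on flat and nanoscale-deformed ("crumpled") graphene
    channels. Generates synthetic ion/DNA particle configurations with
    Gouy-Chapman electric-double-layer structure near flat, sinusoidal and
    trench model surfaces; bins particle frames into molar concentration
    profiles and maps in a distance-from-surface coordinate; computes the
    ionic screening-factor statistic, screening onset, unscreened DNA charge,
    electrostatic potential profiles, Debye lengths and a capacitance proxy;
    models the Dirac-point shift of a graphene channel from unscreened
    charge, including a bandgap-mobility hot-spot mixture; extracts Dirac
    points from gate-voltage sweeps; and fits Sips (Langmuir-Freundlich)
    dose-response isotherms with limit-of-detection estimation against
    negative controls.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
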