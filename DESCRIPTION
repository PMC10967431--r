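Package: pigemit
Title: Mechanistic Simulation of Methane and Ammonia Emissions from
    Fattening-Pig Houses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily-resolution mechanistic simulator of methane and ammonia
    emissions from fattening-pig houses under contrasting manure-management
    systems (long storage in a deep pit versus short storage by daily
    flushing of a shallow sloped-wall pit with partial dilution).  Couples
    Gompertz growth, feed and water curves to excretion mass balances
    (dry matter, volatile solids, nitrogen fractions, water), manure-pit
    geometry and removal scheduling, a mass-transfer ammonia volatilization
    model, and Arrhenius methane kinetics on stored volatile solids.
    Includes the reference-method emission computation from gas
    concentrations and ventilation rates, validation metrics (MAE, RMSE,
    R squared), scenario presets, a synthetic weather generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
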