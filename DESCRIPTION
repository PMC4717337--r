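Package: pikatherm
Title: Coupled Microclimate and Endotherm Heat-Balance Modelling for
    American Pika Thermoregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modelling of behavioural thermoregulation in the
    American pika (Ochotona princeps). Implements an hourly microclimate
    simulator (diurnal air temperature, solar radiation on slopes,
    substrate heat conduction, wind profiles, altitudinal lapse rates)
    coupled to a steady-state heat-balance model of a furred ellipsoidal
    endotherm. The coupled model yields metabolic-chamber simulations,
    thermal-neutral-zone detection, parameter sensitivity analyses,
    temperature-constrained above-talus activity budgets under current
    and warmed climates, and a heat-wave refuge simulation. Companion
    statistical tools reproduce the field analyses: surface lapse-rate
    regression with consistency filtering, talus refuge-offset summaries,
    per-capita activity modelling with AICc model averaging and 85
    percent confidence intervals, temperature-threshold behaviour
    comparisons, and call-rate regressions, all exercised on seeded
    synthetic data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
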