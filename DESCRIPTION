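Package: wetlandC
Title: Carbon Metabolism and Greenhouse-Gas Budgets for Deltaic Wetlands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns replicated field incubations from shallow deltaic wetlands
    into annual carbon and greenhouse-gas budgets. Light/dark oxygen
    incubations of plankton and benthos are converted into areal daily gross
    primary production, net community production and aerobic respiration in
    carbon units; quadrat harvest dry weights into vegetation carbon stocks
    and interval net production; sediment-core headspace readings into areal
    methane fluxes, with exponential temperature and power-law salinity
    response fitting. Dated rates are integrated into annual per-site carbon
    balances, expressed as CO2-equivalents using a mass-based CH4/CO2 factor
    of 28, and extrapolated to wetland-type surfaces. A seeded synthetic-data
    generator emulates the sampling design (bi-monthly campaigns over two
    hydrological cycles across a salinity gradient) so that every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
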