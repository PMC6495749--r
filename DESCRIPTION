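Package: methanofrac
Title: Growth Kinetics and Carbon Isotope Fractionation of Hydrogenotrophic Methanogens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators for growth, methane-production and metabolite kinetics
    of hydrogenotrophic methanogens grown in chemostats and sealed batch
    bottles (specific growth rate, cell yield, cell-specific production rate),
    headspace gas chemistry (isochoric pressure scaling, ideal-gas amounts,
    Henry's-law aqueous concentrations), and carbon isotope systematics
    (delta13C/ratio conversions, alpha and epsilon fractionation factors,
    DIC to CO2(aq) equilibrium correction, closed-system Rayleigh drawdown
    forward simulation and inversion with uncertainty propagation). Includes
    a seeded synthetic-data generator reproducing the statistical structure
    the estimators assume, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
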