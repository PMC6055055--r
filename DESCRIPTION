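Package: canopyflux
Title: Whole-Canopy Gas-Exchange Fluxes, Sun/Shade Canopy Modelling and
    Resource-Use Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-canopy gas exchange measured with
    flow-through canopy chambers. Computes instantaneous canopy transpiration
    and net photosynthesis from chamber CO2 and vapour-pressure differentials,
    estimates night-time respiration and its temperature response, fits
    canopy light- and nitrogen-extinction profiles, and scales leaf
    photosynthesis to the canopy with a two-fraction (sunlit/shaded) model
    combining FvCB biochemistry, coupled stomatal conductance and
    Penman-Monteith transpiration, including stomatal down-regulation under
    limited water supply. Model-based correction factors translate
    chamber-measured fluxes to open-air conditions, and daily canopy
    photosynthetic water-use and nitrogen-use efficiencies are derived with
    sensitivity analyses over canopy size and leaf-nitrogen profiles. A
    synthetic-data module generates weather, chamber logs, canopy profiles
    and night respiration with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    minpack.lm,
    generics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    zoo,
    yaml,
    readr,
    withr
Config/testthat/edition: 3
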