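Package: radonaero
Title: Radon Progeny and Nanoaerosol Exposure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing indoor and outdoor radon short-lived decay
    products (RnDP) together with nanoaerosol number size distributions.
    Implements decay-chain kinetics (Bateman ingrowth of the 222Rn chain),
    progeny exposure metrics (equilibrium equivalent concentration,
    equilibrium factor, unattached fractions, potential alpha-energy,
    working-level-month exposure and an empirical dose-conversion factor),
    SMPS-style size-distribution summaries (totals, geometric-mean diameter,
    sub-cutoff number fractions, surface-area partitions, lognormal GM/GSD
    statistics), a forward model and linear inversion of two-detector
    three-interval gross-alpha counting, and a Jacobi-type indoor room
    kinetics simulator that generates coupled aerosol-spectrum and progeny
    time series with scripted household events for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
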