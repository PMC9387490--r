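Package: fawspread
Title: Climate-Driven Population Growth and Dispersal Simulation for Fall Armyworm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit, weekly-timestep simulator of fall armyworm
    (Spodoptera frugiperda) population growth and spread on regular climate
    grids. Couples a Sharpe-Schoolfield thermal performance curve for positive
    growth with threshold-exceedance stress mortality (cold, heat,
    desiccation), logistic density dependence, short-range kernel dispersal,
    stochastic long-range jumps, and an Allee extinction threshold. Includes a
    synthetic-climate generator emulating gridded 3-hourly land surface
    temperature and wilting-fraction forcing, NetCDF climate I/O, monthly
    growth-rate and establishment mapping, replicate simulation with mass
    accounting, and ggplot2 visualisation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    ncdf4,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    tiff,
    withr
Config/testthat/edition: 3
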