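Package: smokewave
Title: Wildfire Smoke PM2.5 Ensemble Uncertainty and Short-Term Health Impact Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for episodic wildfire-smoke air quality analysis on gridded
    daily-mean PM2.5 fields. Implements the 2x2 factorial ensemble
    decomposition of simulation uncertainty into wildfire-emissions and
    meteorology components, monitor-based model evaluation statistics (mean
    bias, normalized mean error and bias, root mean square error, regression
    slope and R-squared), county-level short-term health impact assessment
    with log-linear concentration-response functions and incidence rate
    ratios with normal-theory confidence intervals, and validation of
    modeled rate ratios against emergency-department visit count series.
    A synthetic plume generator produces factorial ensembles, monitor
    observations, county tables and Poisson visit counts with known ground
    truth so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ncdf4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
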