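Package: smokepolicy
Title: Occupational Wildfire-Smoke Exposure Assessment for Outdoor Workforces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing occupational exposure to wildfire-smoke
    PM2.5 under air-quality-triggered worker-protection rules. Converts
    PM2.5 concentrations to the US EPA Air Quality Index (AQI) and the
    Washington Air Quality Advisory (WAQA) by piecewise-linear breakpoint
    interpolation, implements the EPA NowCast hourly aggregate, ingests
    EPA AQS daily monitor summaries and QCEW-style monthly employment,
    aggregates monitor records to county-day PM2.5 series, tallies
    rule-threshold exceedance days and AQI-category days, computes
    seasonal workforce indices and industry subsector shares, and
    estimates worker-days of exposure and filtering-facepiece respirator
    demand. A synthetic-data generator produces monitor-level PM2.5 and
    monthly employment fixtures with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
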