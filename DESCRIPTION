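Package: pacolloc
Title: Collocation Analysis of Low-Cost Optical PM2.5 Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating low-cost dual-laser optical particle sensors
    (PurpleAir-style) against reference PM2.5 monitors in woodsmoke-affected
    airsheds. Implements the standard conversions from raw sensor output to
    PM2.5 mass (per-unit linear calibrations, the ALT-3.4 particle-count
    conversion, the US EPA humidity-adjusted conversion, and a nephelometer
    woodsmoke relationship), discordance-weighted fusion of the two laser
    channels of one unit, midpoint-based hourly and completeness-gated daily
    aggregation with named exclusion windows, and collocation summary
    statistics (Pearson r, RMSE, reduced-major-axis and ordinary least squares
    slopes). A synthetic-data generator emulates woodsmoke diurnal and seasonal
    structure, dual-channel sensors with one-channel spikes, and an FDMS TEOM
    reference with its 50 percent measurement duty cycle, so the full pipeline
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
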