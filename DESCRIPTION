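Package: vesselbird
Title: Detecting Seabird-Fishing Vessel Interactions from Biologging and
    VMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying individual interactions
    between GPS/accelerometer-tracked central-place-foraging seabirds and
    GPS-monitored fishing vessels. Classifies bird behaviour (sitting on
    the water, flapping and gliding flight) from tri-axial acceleration
    via VeDBA and spectral clustering, regularizes Vessel Monitoring
    System pings onto a common time grid, segments foraging trips and
    computes movement metrics, detects approach events from joint
    bird-vessel geometry, estimates the interaction distance as the
    breakpoint of a two-segment regression on the sitting-behaviour
    distance profile, and runs the downstream group comparisons (linear
    mixed models, chi-square tests). Includes a synthetic-data generator
    that emits all data streams with complete ground truth so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lubridate,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
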