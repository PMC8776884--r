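Package: fleetres
Title: Fishing-Fleet Resilience Assessment from Vessel-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the resilience of fishing fleets to forced
    reductions of fishing effort. Classifies vessel activity by gear from
    AIS-style position reports, grids fishing hours onto regular lat-lon
    cells with log-normal low/medium/high classification, tracks monthly
    effort-weighted barycentres, quantifies spatial overlap with endangered,
    threatened and protected (ETP) species ranges, and -- at its core --
    treats a fleet's monthly fishing hours as a stock-abundance index and
    fits Schaefer surplus-production dynamics by viable-pair Monte-Carlo
    sampling to estimate the fleet's intrinsic growth rate, maximum
    sustainable fishing hours, maximum sustainable reduction (MSR) and a
    monthly relative-stress series. A synthetic-data module generates AIS
    tracks, effort series and species-richness grids so the full pipeline
    is testable without proprietary inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
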