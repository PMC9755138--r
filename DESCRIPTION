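Package: dielmove
Title: Diel and Seasonal Activity Patterns from GPS Telemetry and
    Accelerometer Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising daily and seasonal activity of
    GPS-collared predators and their prey. Provides GPS track screening
    (gross-outlier and movement-spike removal, fix-cadence filtering,
    post-capture trimming, kill-site and cub-period exclusion windows),
    a solar and lunar ephemeris with the suntime transformation that
    calibrates clock times to sunrise, solar noon and sunset,
    Metropolis-Hastings sampling of suntime activity distributions with
    von Mises kernel density estimates, coefficients of activity overlap
    and day/night activity proportions, accelerometer activity metrics,
    hierarchical-bootstrap monthly displacement estimates, penalized
    cyclic harmonic seasonal curves, and a fully labelled synthetic
    telemetry generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
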