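Package: parkscore
Title: Daily Symptom and Self-Management Scores for Parkinson Disease Home Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw home-monitoring event streams for people with
    Parkinson disease (dispenser-logged medication intakes, bed-sensor
    occupancy intervals, wrist-sensor bradykinesia and dyskinesia samples,
    and self-reported meals, exercise and quality-of-life responses) into
    per-day scores on a common 0-100 scale: medication timing compliance,
    a Pittsburgh Sleep Quality Index style sleep score, two motor scores,
    meal timing compliance, physical activity against an individual target
    and quality of life. Includes rolling summaries with traffic-light
    bands, lagged cross-score correlation, and a seeded multi-stream
    scenario simulator with ground truth for end-to-end testing without
    device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
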