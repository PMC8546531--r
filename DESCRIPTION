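Package: gaitbelt
Title: Daily-Life Gait Speed from a Belt-Worn Accelerometer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measurement chain for free-living gait speed from a belt-worn
    triaxial accelerometer: peak-based step detection, step intervals
    quantized to a 0.1-second grid, stride-length estimation from a
    sex-specific constant times body height, walking-bout segmentation and
    bout-level speed. Adds daily-life gait analytics (diurnal and weekly
    profiles, percentile relative to usual gait speed, dispersion),
    sarcopenia classification under the Asian Working Group for Sarcopenia
    (AWGS) rule, a cohort statistics layer (group comparisons, Pearson
    correlation matrices, linear regression with standardized coefficients
    and variance inflation factors), step-detection validation metrics, and
    a synthetic-data generator that produces walking signals with known step
    times and multi-day cohorts with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils
Suggests:
    car,
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
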