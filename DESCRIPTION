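Package: msdetect
Title: Parameterized Velocity-Threshold Detection and Analysis of
    Microsaccades in High-Frequency Gaze Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and exploratory analysis of microsaccades and
    saccades in high-frequency (>= 200 Hz) eye-tracking recordings using
    a fully parameterized elliptic velocity-threshold filter with
    median-based robust dispersion estimation.  Supports monocular,
    averaged-eye and binocular detection, glissade exclusion windows,
    inter-saccadic-interval enforcement, amplitude/duration/peak-velocity
    bounds, derivation of fixations as inter-saccade intervals, circular
    direction statistics with rose-plot binning, rotation of microsaccade
    directions toward the next fixation, temporal-position and
    main-sequence summaries, multi-level aggregation, a plain-text trial
    interchange format, and a seeded synthetic gaze simulator with ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
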