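Package: finsong
Title: Fin Whale 20 Hz Song Analysis from Duty-Cycled Hydrophone Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fin whale (Balaenoptera physalus) 20 Hz song
    recorded by duty-cycled passive acoustic monitoring buoys. Provides a
    synthetic-deployment generator (downswept 20 Hz notes, song sequences with
    short and long inter-note-interval patterning, breath gaps, coloured
    ambient noise, duty-cycled WAV recordings with ground-truth selection
    tables), Raven-style selection-table I/O, spectrogram-based note
    measurements (inband power, peak/center frequency, 90 percent bandwidth,
    SNR against auto-generated noise windows), inter-note-interval (INI)
    construction and filtering, seasonal trend modelling with cyclic-spline
    generalized additive mixed models, and classification of songs and song
    years into short-INI, long-INI and seasonal-shift patterns.
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
    lubridate,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
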