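Package: ovispindle
Title: Sleep Spindle Detection and State-Space Analysis for Ovine EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and characterizes sleep spindles in multichannel
    cortical EEG recordings, following an automated wavelet power-envelope
    algorithm developed for sheep polysomnography. Provides reading and
    writing of European Data Format (EDF) and delimited-text recordings,
    anti-aliased downsampling and common-average re-referencing, spindle
    detection with prominence-based boundary refinement and shape filters,
    local/simultaneous spindle topography with connectivity matrices,
    spindle-slow-wave coupling (peak-to-peak amplitude and phase), sleep
    cycle segmentation with delta-power NREM substaging and density
    profiles, spectral-ratio state-space density maps, and a synthetic
    polysomnography generator with ground-truth event tables for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
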