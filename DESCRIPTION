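Package: ppgrr
Title: Respiratory Rate Estimation from Photoplethysmography Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates respiratory rate (RR) from contact or remote
    photoplethysmography (PPG) time series by three families of signal
    processing methods: morphological extraction of respiratory-induced
    variations (baseline, amplitude and frequency modulations) via
    incremental merge segmentation with mean/median/PCA fusion, empirical
    mode decomposition by iterative sifting, and singular spectrum
    analysis.  Includes periodogram-based RR picking with a heart-rate
    adaptive search band, quality screening of respiratory reference
    signals, error metrics, Bland-Altman agreement analysis, a
    Friedman/Nemenyi rank-comparison framework with robust effect sizes,
    and a seeded synthetic PPG simulator with controllable respiratory
    modulations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    yaml
Config/testthat/edition: 3
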