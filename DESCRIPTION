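Package: eggwave
Title: Multi-Channel Electrogastrogram Spectral Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reads multi-channel cutaneous electrogastrogram (EGG) recordings
    in a simple 8-row-header ASCII format, extracts the gastric slow-wave band
    (0.5-9 cpm), downsamples high-rate recordings to 4 Hz, flags movement
    artifacts by standard-deviation thresholding, and computes running and
    overall spectral analyses (Tukey/Bartlett-Hann/Hann periodograms and
    Burg autoregressive spectra with AIC order selection). Derives the
    clinically established gastric-rhythm parameters: dominant frequency and
    power, normogastria index, rhythm-class percentages, instability
    coefficients, slow-wave coupling, band power distribution and the
    fed/fast power ratio. For recordings sampled fast enough to contain the
    ECG, an optional heart-rate-variability sub-pipeline provides Pan-Tompkins
    R-peak detection, cubic-spline RR resampling and standard time- and
    frequency-domain indices. A synthetic-signal generator produces
    sine-plus-noise validation records and ECG-like signals with known RR
    modulation so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    pracma,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
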