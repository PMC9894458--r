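Package: vibemg
Title: Staging Venous Occlusion from Vibration-Evoked Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for classifying stages of deep vein
    thrombosis (venous occlusion) from surface electromyography recorded
    during 40-50 Hz vibrotactile stimulation of a relaxed muscle. Raw EMG
    is segmented into 400-sample windows, converted to 95x3 short-time
    Fourier magnitude spectrograms, percentile min-max normalized, reduced
    to 25 principal-component scores arranged in a 5x5 center-out grid,
    and classified with a small two-branch convolutional network trained
    by stochastic gradient descent with momentum. Within-leg 10-fold and
    leave-one-leg-out cross-validation protocols are provided, together
    with a seeded synthetic-EMG generator that reproduces the spectral
    structure the analysis assumes, so the whole pipeline is testable
    without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    readxl,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'utils.R'
    'signal_io.R'
    'preprocess.R'
    'features.R'
    'cnn.R'
    'evaluation.R'
    'synthetic.R'
    'cli.R'
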