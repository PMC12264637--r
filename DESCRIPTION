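Package: auscultate
Title: Lung Sound Classification with Stethoscope Filter Modes, Acoustic
    Features and a Multi-Layer Perceptron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for binary (healthy vs unhealthy) classification of
    auscultation recordings. Emulates the three electronic-stethoscope filter
    modes (Bell 20-200 Hz, Diaphragm 100-500 Hz, Extended 50-500 Hz), extracts
    five acoustic features (energy, band power, zero-crossing rate, spectral
    centroid, mel-frequency cepstral coefficients) per mode for a 15-element
    feature vector per recording, and trains a from-scratch multi-layer
    perceptron (15-30-20-1, tansig hidden layers, linear output) by full-batch
    backpropagation. Includes WAV input/output, dataset splitting,
    confusion-matrix diagnostics, an architecture-search harness, and a seeded
    synthetic respiratory-sound simulator (breath-noise envelopes, wheezes,
    crackles, heart-sound contamination) so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
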