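Package: chicksex
Title: Chick Sex Detection from Day-Old Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects the sex of day-old chicks from their distress calls.
    Recordings are high-pass filtered, segmented into individual calls by
    short-time zero-crossing-rate endpoint detection with duration gating,
    and each call is converted to one of three time-frequency features
    (dB spectrogram, cepstrogram, or a combined MFCC + log mel-filterbank
    matrix). Configurable neural classifiers (CNN, GRU, CRNN, two-stream
    and a reduced ResNet-50) score each call, and a bird's sex is decided
    by majority vote over 41 calls. A synthetic call generator with known
    ground truth makes every stage testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
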