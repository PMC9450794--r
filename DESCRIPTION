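Package: snoredetect
Title: Automatic Snore Detection in Low-Rate Polysomnography Snore Channels
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects snoring events in the low-sampling-rate (200 Hz) electric
    snore channel recorded during polysomnography. Implements a windowed
    root-mean-square envelope, moving-average smoothing, hysteresis event
    segmentation and a 0.6-2 s duration gate; validates detector output
    against observer annotations with confusion-matrix metrics and Cohen's
    kappa; compares snore-event durations between primary snorers and
    obstructive sleep apnea (OSAHS) patients with two-sample t-tests; and
    ships a synthetic snore-channel simulator with ground truth so the whole
    pipeline is testable without clinical recordings. Includes readers and
    writers for WAV, CSV and EDF signals and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, signal, jsonlite, optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
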