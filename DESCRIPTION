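Package: respfusion
Title: Multimodal In-Vehicle Respiratory Rate Detection by Signal Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects breathing events in multichannel in-cabin recordings
    (seat-belt piezoelectric pressure, seat-belt and seat accelerometers,
    two video-derived region-of-interest traces) against a chest-belt
    reference. Implements reference-channel spectral noise suppression of
    seat-belt accelerometry, green-channel ROI signal extraction from video
    frames, sliding-window snippet segmentation with binary breathing-event
    labels, four convolutional-network fusion strategies (early,
    signal-based late, sensor-based late, hybrid majority vote) with a
    self-contained training engine, a leave-one-subject-out evaluation
    harness with the performance metric P = (PPV + S)/2, and a synthetic
    multimodal recording simulator with exact ground-truth breathing peaks
    so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
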