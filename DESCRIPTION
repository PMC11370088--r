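Package: trackbias
Title: Sampling-Interval Bias in Fine-Scale GPS Tracking of Flying Seabirds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how the sampling interval of GPS tracking data biases
    movement metrics of flying seabirds. From 1 Hz logger fixes (or synthetic
    stand-ins) it cleans and segments paths into flights, classifies flights
    as straight or sinuous by a straightness index, builds a Doppler
    point-speed reference path, sub-samples flights at intervals of 1 s to
    1 h, and computes proportional-distance and per-point distance, speed and
    turning-angle biases. A 3-state Gaussian hidden Markov model on step
    speed and turning angle, with kernel utilization distributions and
    volume-of-intersection overlap, quantifies how inferred behavioural
    states drift with the sampling interval.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
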