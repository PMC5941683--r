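Package: ehgdetect
Title: Automated Detection of Uterine Contractions from Multichannel
    Electrohysterograms
Version: 0.1.0
Authors@R:
    person("EHG", "Tools", email = "ehgtools@example.org", role = c("aut", "cre"))
Description: Detects uterine contractions in multichannel surface
    electrohysterogram (EHG) recordings. Derives 12 vertical bipolar signals
    from a 4x4 abdominal electrode grid, band-pass filters them to the
    uterine EMG band (0.1-3 Hz), computes the nonlinear correlation
    coefficient H2 between the 36 laterally adjacent bipolar pairs over a
    sliding window, thresholds the resulting correlated-pair count curve
    into candidate events, and post-processes them by fusion of nearby
    events and elimination of brief ones. Includes an event-matching
    evaluator (full/partial detections, misses, false alarms), a seeded
    synthetic EHG generator with ground-truth annotations, readers and
    writers for EDF and delimited-text recordings, and a command-line
    interface tying simulation, detection and evaluation together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
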