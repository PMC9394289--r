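Package: crgcn
Title: Channel-Relationship Graph Convolutional Networks for EEG Emotion
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies emotional valence and arousal from multichannel EEG
    using a Chebyshev spectral graph convolutional network whose adjacency
    matrix fuses electrode-distance topology with thresholded Pearson
    functional connectivity. Provides baseline calibration and sliding-window
    segmentation of DEAP-layout trials, band-wise power spectral density
    node features with z-score normalization, distance/connectivity/fused
    channel-graph construction with scaled-Laplacian Chebyshev filtering,
    a seeded training loop, cross-validated subject-dependent and
    subject-independent evaluation with accuracy and F1, ablation harnesses
    over adjacency variants and normalization, and a synthetic DEAP-shaped
    EEG generator with known class structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
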