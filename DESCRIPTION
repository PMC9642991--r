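Package: edgecode
Title: Edge-Orientation Coding in First-Order Tactile Afferents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for studying how single fast-adapting (FA-1)
    and slow-adapting (SA-1) type 1 tactile afferents signal the orientation
    of raised edges scanned across the fingertip at different speeds.
    Provides a generative subfield model of afferent receptive fields, trial
    segmentation and time-to-space conversion of spike trains against a drum
    position trace, intensity and firing-rate-profile response measures,
    ideal-observer leave-one-trial-out classification of edge orientation
    within and across scanning speeds (temporal and spatial domains),
    Gaussian-kernel estimation of the spatial precision of spiking, and
    summary statistics with above-chance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
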