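Package: wormfms
Title: Fractional Mobility Scoring for Multiwell C. elegans Drug Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies acute drug effects on Caenorhabditis elegans
    movement from time-lapse images of 96-well plates. Each well is imaged
    twice in quick succession at every timepoint; a fractional mobility
    score (FMS) is computed as the proportion of worm-associated pixels
    that moved between the two frames, using Sobel edge detection,
    adaptive thresholding, and binary closing to segment worms. Downstream
    tools normalize scores to drug-free controls, fit three-parameter
    logistic or exponential dose-response curves to extract EC50 values,
    and compute proportional recovery scores for paralysis-then-recovery
    time courses. A synthetic well-image generator with pixel-level ground
    truth makes the entire pipeline testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
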