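Package: patchcamo
Title: Quantifying Colour-Based Background-Matching Camouflage in Patchy Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying background-matching camouflage of uniform
    colour targets in patchy natural scenes. Provides CIELab colour conversion
    and the CIEDE2000 colour-difference metric; design of microhabitat
    "specialist" and whole-scene "generalist" target colours, including a
    paint-matching selection rule; edge-preserving ranked smoothing, naive
    Bayes microhabitat segmentation and connected-component patch statistics;
    near-zone construction and target-background colour contrast predictors;
    generation of visual-search stimulus databases and constrained slide
    sets; and detection-risk modelling via a relative-detection-distance
    survival transform with Cox proportional-hazards fits (Gaussian
    frailties), likelihood-ratio tests, AIC ladders and proportional-hazards
    diagnostics. A synthetic-data module generates patchy multi-microhabitat
    scenes with ground truth and detection trials with known hazard
    structure, so the full pipeline is testable end to end.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    survival,
    jsonlite,
    png,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
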