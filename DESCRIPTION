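Package: gazeFRP
Title: Fixation-Related Potentials for Hybrid Eye-Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline analysis pipeline for dwell-based gaze interaction
    augmented with EEG: dispersion-based dwell detection with refractory
    rules, extraction of EOG-safe fixation-related potential (FRP) epochs,
    windowed-amplitude feature vectors over posterior channels, single-trial
    classification of intentional versus spontaneous fixations with a
    shrinkage-regularized LDA and a committee of greedily selected threshold
    classifiers, and specificity-calibrated cross-validated evaluation.
    Includes a synthetic gaze+EEG session generator emulating the
    stimulus-preceding-negativity-like slow wave that separates controlling
    from spontaneous fixations, so the full pipeline is testable without
    human recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
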