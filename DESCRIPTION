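Package: hdsync
Title: Coordinated Head-Direction Population Analysis Across Brain Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for simultaneously recorded head-direction (HD)
    populations in two brain regions: occupancy-normalized tuning curves and
    shuffle-based HD-cell classification, von Mises tuning-curve fitting,
    population decoding of heading with a linear-Gaussian model (ridge
    regression on the sine and cosine of heading), cue-rotation realignment
    and inter-regional lag analysis of decoded errors, darkness drift
    correlation, putative monosynaptic connection detection from 0.5 ms
    cross-correlograms, and fast-/regular-spiking waveform classification.
    Includes a synthetic session generator with full ground truth (von
    Mises-tuned Poisson units in two regions driven by one latent heading,
    reference-frame rotations and drift, embedded spike transmission) used
    to validate every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    withr,
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
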