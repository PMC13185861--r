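Package: botmetrics
Title: Kinematics, Spectral Complexity and Expression Variability for
    Self-Motile Ciliated Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of self-motile mucociliary organoids
    ("biobots") and their neuron-implanted counterparts. Provides trajectory
    kinematics (distance, speed, acceleration, minimum speed, arena coverage),
    a spectral movement Complexity Index built from Welch power spectral
    densities of the x and y coordinate series with phase-randomized
    surrogate validation of spectral peaks in wavelet space, morphometric
    shape indices from binary body masks, and a pooled-sample gene-expression
    variability analysis that reconstructs individual-level coefficients of
    variation from pool replicates and tests abundance-ranked percentile bins
    with a pair-preserving permutation test. A synthetic-data module
    generates trajectories, elliptical masks and pooled count matrices with
    known ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
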