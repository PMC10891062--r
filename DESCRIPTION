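Package: ipbalance
Title: Iterative Pseudo-Balancing for Semi-Supervised Microscopy Image
    Classification
Version: 0.1.0
Authors@R:
    person("IPB", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-supervised classification of phase-contrast stem-cell
    colony images under severe class imbalance.  Implements a
    student-teacher meta-pseudo-label training loop in which the teacher's
    pseudo-labels drive per-epoch multinomial resampling with
    inverse-proportion class weights, so the student always sees a balanced
    stream of patches ("iterative pseudo-balancing").  Ships the full
    supporting stack: a seeded synthetic colony-image generator with four
    texture-separable morphology classes and multi-label composites, the
    six-step morphological colony segmentation pipeline (Gaussian blur,
    local entropy, Otsu, opening, hole filling, small-object removal),
    in-mask multi-scale patch sampling (224/112 pairs or single 128),
    stochastic augmentation, a compact convolutional classifier framework
    with Kaiming initialisation and SGD training written in base R, and
    per-class TPR/F1 evaluation with stratified cross-validation splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
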