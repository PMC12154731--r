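Package: lapnet
Title: Substrate-Activation Detection from Laplacian Electron-Density Contour Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects activated (reactive) enzyme-substrate states in hydrolases
    from per-frame electronic structure. Evaluates the electron density and its
    Laplacian analytically from Gaussian-basis wavefunctions (Molden format) in
    the plane of the substrate carbonyl group and the attacking nucleophile,
    reduces each map to its zero-isovalue contour, renders and crops
    carbonyl-only images, and classifies frames as reactive or non-reactive
    with a small convolutional neural network trained with early stopping, or
    with a rule-based valence-shell probe. Per-frame labels, confidences and
    nucleophilic-attack distances are aggregated into trajectory-level
    activation-efficiency statistics: reactive fraction, run-length and
    randomness analysis of state alternation, confidence summaries, and
    Gaussian-mixture decomposition of attack-distance distributions. A
    synthetic promolecular-wavefunction and contour-image generator makes the
    whole pipeline testable without a quantum-chemistry engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    Matrix,
    optparse,
    png,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
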