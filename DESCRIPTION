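Package: micsp
Title: Multi-Class Common Spatial Patterns and Spectral Features for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification for seven-class (simple and
    compound limb) motor-imagery EEG. Implements the preprocessing chain
    (common average reference, zero-phase band-pass, anti-aliased
    downsampling, interval cropping), event-related spectral perturbation
    (ERSP) maps with band-power comparisons, power spectral entropy, a spatial
    distribution coefficient, and three one-versus-rest multi-class common
    spatial pattern variants (Multi-CSP, Multi-GECSP and stationary Tikhonov
    regularized Multi-sTRCSP) with log-variance features, a built-in linear
    support vector machine and stratified tenfold cross-validation. A
    synthetic EEG generator with planted sensorimotor sources and known mixing
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    rhdf5,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
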