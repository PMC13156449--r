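Package: naheart
Title: Quantitative Cardiac Sodium MRI Simulation, Motion and B1 Bias
    Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative myocardial sodium (23Na) MRI with an
    interleaved 23Na/1H radial acquisition. Provides a dynamic digital
    torso phantom with respiratory and cardiac motion, a 3D golden-angle
    radial k-space simulator and gridding (NUFFT) reconstruction,
    navigator-based respiratory and cardiac self-gating, rigid k-space
    respiratory motion correction, nonrigid cardiac motion correction,
    an anatomy-based B1 bias-field correction with region-spread-function
    partial-volume correction, relaxation correction, and apparent tissue
    sodium concentration quantification with repeatability statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    signal,
    RNifti,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
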