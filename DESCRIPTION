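Package: tiltnorm
Title: Normative Analysis of 3D Surface Tilt Estimation from Stereo Images
Version: 0.1.0
Authors@R: person("tiltnorm", "developers", role = c("aut", "cre"),
    email = "tiltnorm@example.org")
Description: Tools for studying how well local surface tilt (the direction of
    surface slant) can be estimated from binocular images of textured scenes.
    The package renders synthetic stereo image pairs with pixel-registered
    range maps, computes groundtruth tilt, slant and local tilt variance from
    the range data, measures three local image cues (luminance-gradient,
    disparity-gradient and texture-spectrum orientations), trains a
    nonparametric minimum mean squared error estimator over quantized cue
    triplets (an "estimate cube"), and provides circular statistics for axial
    data together with a psychophysics-style evaluation pipeline (conditional
    error distributions, bias-corrected trial-by-trial correlations,
    covariate effects and Monte Carlo confidence bands).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
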