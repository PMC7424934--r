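Package: mirlight
Title: Markov Illuminance and Reflectance Model of Lightness Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a conditional random field model of human lightness
    perception on 16x16 grid stimuli. The model factors an observed luminance
    image into hidden illuminance and reflectance layers using simple
    probabilistic assumptions about lighting and surfaces (a bounded
    reflectance range, a preference for low illuminance, rarity and
    straightness of lighting boundaries, X-junctions as lighting-edge
    evidence, and region-wise cost evaluation), and finds the maximum a
    posteriori decomposition by max-sum loopy belief propagation over 2x2
    patch cliques. Ships generators for a battery of classic lightness
    illusions (argyle, Koffka rings, snake, White's, checkerboard
    assimilation, simultaneous contrast, haze), three comparison models
    (oriented difference-of-Gaussians, high-pass filtering, and multiscale
    McCann retinex), a qualitative illusion-prediction harness, phenomena
    probes (highest-luminance anchoring, glow, codetermination,
    articulation), and utilities for scoring two-alternative forced-choice
    lightness judgments with Wilson confidence intervals.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
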