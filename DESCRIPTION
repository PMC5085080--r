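Package: gridslam
Title: Probabilistic Grid-Cell SLAM Simulation and Spatial Firing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates simultaneous localization and mapping (SLAM) by a
    population code of grid cells and boundary-vector cells. A
    Rao-Blackwellized particle filter fuses noisy self-motion cues,
    egocentric boundary observations and an intermittent compass cue to
    jointly estimate pose (multi-module grid phases) and a learned map
    (grid-to-boundary association weights). Includes seeded arena and
    trajectory generators (open arenas, hairpin and spiral corridor mazes),
    inhomogeneous Poisson spike simulation, and a full rate-map analysis
    stack: occupancy-normalized rate maps, spatial autocorrelograms,
    gridness and border scores, grid template fitting, parametric rate-map
    classification, arm-arm correlation matrices, directional information,
    rescaling and attractor diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
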