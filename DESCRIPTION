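Package: respmorph
Title: Geometric Morphometrics of Chest-Wall Breathing Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based three-dimensional shape analysis of chest-wall
    breathing motion recorded with optoelectronic-plethysmography-style marker
    systems. Computes enclosed chest-wall volume signals from closed marker
    meshes, detects end-expiratory and end-inspiratory instants, estimates
    missing markers by thin-plate splines, superimposes landmark
    configurations by generalized Procrustes analysis, performs shape-space
    principal component analysis, derives functional size and functional
    shape statistics per subject and breathing condition, runs a paired
    Wilcoxon signed-rank hypothesis battery contrasting quiet and
    post-exercise recovery breathing across postures, and warps triangulated
    torso meshes between breathing states. Includes a synthetic chest-wall
    motion generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
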