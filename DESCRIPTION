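Package: slowcv
Title: Slow Feature Analysis Collective Variables for Enhanced Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers slow collective variables from molecular dynamics
    trajectories by slow feature analysis (SFA) on periodic dihedral
    features, exports them as PLUMED input for well-tempered (and
    funnel-augmented) metadynamics, and reweights the resulting biased
    sampling into free-energy surfaces with the Tiwary-Parrinello
    estimator. Includes a self-contained toy engine (telegraph dihedral
    series, overdamped Langevin dynamics, a toy well-tempered
    metadynamics integrator) so the whole pipeline can be exercised and
    validated without any external MD software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
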