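Package: t1moco
Title: Groupwise Motion Correction for Cardiac T1 Mapping
Version: 0.1.0
Authors@R: person("t1moco", "developers", role = c("aut", "cre"),
    email = "t1moco@example.org")
Description: Respiratory motion correction for inversion-recovery cardiac T1
    mapping. Implements a groupwise, multi-scale, coarse-to-fine deformable
    registration network that estimates the inverse displacement vector
    fields aligning the seven inversion-recovery-weighted images of a
    ShMOLLI-style acquisition, trained by self-supervision on synthetically
    deformed motion-free stacks. Ships a short-axis cardiac phantom
    simulator with a magnitude inversion-recovery signal model, displacement
    vector field algebra (generation, mean removal, warping, composition,
    numerical inversion), pixel-wise three-parameter T1 and R-squared map
    reconstruction with Look-Locker correction, inverse-variance observer
    score pooling, and paired Wilcoxon comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
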