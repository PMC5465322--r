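Package: epiboly
Title: Three-Force Modelling and Trajectory Analytics of Deep-Cell-Layer
    Spreading During Killifish Epiboly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation and analysis of embryonic deep-cell-layer
    (DCL) spreading over the extra-embryonic enveloping layer (EVL) on the
    spherical egg of annual killifish. Implements the three-force interacting
    point-particle model (EVL vertex-spring network with a constant-velocity
    epibolic margin; DCL particles under soft-sphere repulsion, Gaussian
    attraction to EVL cell borders, barycentric drag by the EVL, and diffusive
    noise), together with the trajectory analytics used to quantify it:
    spherical geometry (algebraic sphere fitting, geodesics, spherical polygon
    areas, rotational drift removal), track linking and quality control, mean
    square displacement and diffusion estimation, decomposition of DCL motion
    into EVL-advected and autonomous components, second-moment cell-shape
    indices and protrusion classification, and Nelder-Mead fitting of the
    simulation to track statistics. Synthetic-data generators provide every
    input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    Rcpp,
    deldir,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
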