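Package: morphocanvas
Title: Polarity-Driven Anisotropic Tissue Growth by Finite Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the morphogenesis of thin biological tissues ("canvases")
    in which gene-like regulatory factors and a propagating polariser field
    specify anisotropic growth, and linear elasticity turns specified growth
    into resultant shape change. The tissue is discretised as a single layer
    of pentahedral (wedge) finite elements spanning two surfaces; signalling
    factors diffuse, decay and are diluted by growth on the deforming midplane
    mesh; residual strain may be dissipated or retained and later released by
    cutting; mesh quality is maintained by two-threshold edge splitting with
    butterfly interpolation. Includes built-in canvas generators, a library of
    named model presets, clone tracking diagnostics, VTK/PLY/OBJ export and a
    command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
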