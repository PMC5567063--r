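Package: mandibleFEA
Title: Plane-Stress Finite Element Analysis and Comparative Statistics for
    2D Mandible Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative biomechanics of two-dimensional mandible models.
    Provides a linear-elastic plane-stress finite element solver for 8-node
    serendipity quadrilateral (QUAD8) meshes, construction of bite-point
    loading scenarios with quasi-homothetic muscle-force scaling,
    mesh-weighted von Mises stress summaries (area-weighted mean, median and
    percentiles with quasi-ideal-mesh error diagnostics), two-way PERMANOVA
    of stress summaries against diet and food-hardness factors, Pagel's
    lambda phylogenetic signal estimation, Brownian-motion ancestral state
    reconstruction, and a parametric generator of synthetic mandible cohorts
    with matching phylogenies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    phytools,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
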