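Package: squamorph
Title: Phylogenetic Geometric Morphometrics of Skull Shape Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for landmark-based geometric
    morphometrics in a phylogenetic context, motivated by the inference of
    ancestral ecologies from skull shape in squamate reptiles. Provides TPS
    landmark file input/output, Generalized Procrustes Analysis with tangent
    space projection, principal-component morphospaces, multivariate
    allometry regression on phylogenetically independent contrasts,
    thin-plate spline warping, squared-change parsimony ancestral state
    reconstruction for shape and size, the multivariate K statistic of
    phylogenetic signal, distance-based convergence measures (C1-C4) with
    Brownian-motion significance tests, MANOVA and phylogenetic MANOVA,
    linear discriminant prediction of ancestral habitat classes, ontogenetic
    trajectory analysis, heterochrony classification, and a synthetic-study
    generator that emulates the statistical structure such analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
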