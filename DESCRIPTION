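Package: maxsdm
Title: Maximum-Entropy Species Distribution Modelling with Consensus
    Uncertainty Refinement
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Presence-background species distribution modelling with a
    maximum-entropy model restricted to linear and quadratic features.
    Provides combinatorial bioclimatic-variable selection (correlation
    grouping, variance-inflation screening, AICc ranking), k-fold
    cross-validation with maximum sensitivity-plus-specificity
    thresholding, ensemble consensus ("refined") suitability maps that
    retain only pixels predicted suitable by at least 95 percent of the
    cross-validation models, projection onto alternative climate
    scenarios, and km2-scale range accounting (suitability bands,
    gains, losses, overlaps, protected-area coverage).  A virtual
    species simulator generates spatially smooth, correlated climate
    landscapes, occurrence samples and scenario shifts so the whole
    pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
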