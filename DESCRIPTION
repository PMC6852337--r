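Package: betascape
Title: Partitioning Landscape Beta-Diversity into Niche and Dispersal
    Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating forest canopy beta-diversity from imaging
    spectroscopy (quality filtering, brightness normalisation, spectral
    "species" clustering and gridded Bray-Curtis dissimilarity), quantifying
    its spatial structure (Mantel tests and bootstrap correlograms with
    Sturges truncation), partitioning it into distance, environment and
    covariance components with monotone I-spline generalised dissimilarity
    models, and confronting it with spatially explicit neutral coalescent
    simulations using fat-tailed dispersal kernels to infer dispersal and
    speciation parameters. A synthetic landscape, community and
    hyperspectral-scene generator with known ground truth lets the whole
    workflow run end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    Rcpp,
    rlang,
    splines,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
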