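Package: coarsesdm
Title: Quantifying the Bias of County-Resolution Occurrence Data in
    Species Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained virtual-ecologist pipeline for measuring how
    occurrence records georeferenced only to an administrative unit (a county)
    bias presence-background species distribution models relative to models
    built from true point localities. Generates synthetic landscapes (spatially
    autocorrelated monthly climate normals, a county tessellation with a
    small-homogeneous-county region and a large-heterogeneous-county region,
    virtual species with known unimodal climatic niches), derives the 19
    bioclim variables, normalizes and reduces them by principal component
    analysis, builds five training-data treatments per species (true
    localities, county centroids, county environmental averages, and 50/50
    mixes), fits an L1-regularized maximum-entropy model to each, and compares
    the fitted models by AUC, thresholded range area, overprediction ratios,
    and the niche-overlap statistics Schoener's D, Hellinger-based I, and
    relative rank.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
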