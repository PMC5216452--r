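Package: natrisk
Title: Naturalization-Risk Mapping from Stacked Ensemble Species Distribution Models
Version: 0.1.0
Authors@R: person("natrisk", "maintainers", email = "natrisk@example.org", role = c("aut", "cre"))
Description: A configurable pipeline for mapping the risk that ornamental
    garden plants naturalize under current and future climates. Covers
    occurrence cleaning on a 10-arcminute geographic grid, pseudo-absence
    design, ensemble species distribution models (GLM, GAM, boosted
    regression trees, random forest) evaluated by the true skill statistic,
    TSS-weighted family ensembles with max-TSS binarization and an AND
    consensus, permutation tests of mean range change, stacked-richness
    hotspot delineation, and land-cover-weighted risk maps. Includes a
    synthetic-data module (spatially autocorrelated climate, Gaussian-niche
    virtual species, presence-only sampling, categorical land cover) so the
    whole pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
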