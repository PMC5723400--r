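Package: clonalscape
Title: Clonal Richness of Tropical Seagrasses and Its Environmental Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies seagrass clones (multilocus genotypes) from
    microsatellite or SNP genotype tables, quantifies marker power via the
    probability of identity, and computes clonal richness R = (G - 1)/(N - 1)
    per site. Converts storm wind/wave time series into annual probabilities
    of exposure to cyclonic seas via a Poisson event model, and infers
    environmental drivers of clonal richness by full-subset additive-model
    selection with AICc ranking, a parsimony rule, and Akaike-weight variable
    importance. Includes cross-species and latitudinal comparisons and a
    synthetic-data generator (clonal populations, storm histories, and
    covariate-response scenarios) so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    igraph,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
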