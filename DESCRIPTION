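Package: cslink
Title: Linked Population and Health-Facility Analysis of Caesarean Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for linked analysis of household-survey and health-facility
    data on caesarean delivery. Provides Euclidean-buffer geolinkage of survey
    clusters to caesarean-providing facilities, principal-component service
    availability and readiness scores, a three-level Bayesian hierarchical
    logistic model fitted by Metropolis-within-Gibbs sampling with latent-scale
    intraclass correlations, proportional change in variance and DIC, a spatial
    hotspot suite (global Moran's I, incremental spatial autocorrelation,
    Getis-Ord Gi* with false-discovery-rate correction), and Moran-eigenvector
    spatially varying coefficient regression on cluster-level counts. A
    synthetic-data generator with known ground truth supports end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
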