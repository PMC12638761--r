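Package: BrainNetMed
Title: Coherence Networks, Polygenic Scores and Regularized Mediation for
    General Intelligence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links genome-wide polygenic scores, resting-state EEG
    coherence-network graph metrics, and the general factor of intelligence
    in one reproducible pipeline. Builds band-specific spectral-coherence
    networks from region-of-interest time series, applies Holm-Bonferroni
    edge pruning and weighted efficiency and clustering graph metrics,
    estimates g from a fixed second-order confirmatory factor model,
    computes clumping-and-thresholding polygenic scores with best-fit
    threshold search and permutation correction, and performs global and
    regularized region-specific (elastic-net) exploratory mediation with
    unpenalized re-estimation of selected mediators. Test-retest
    reliability of all graph metrics is quantified by ICC(3,1). A seeded
    synthetic-cohort generator with planted genetic, network and
    mediation effects makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'BrainNetMed-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'bands.R'
    'connectivity.R'
    'graphMetrics.R'
    'gfactor.R'
    'genetics.R'
    'elasticNet.R'
    'mediation.R'
    'reliability.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
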