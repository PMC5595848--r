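Package: larvalGut
Title: Bayesian Analysis of Caterpillar Gut Microbiome Variation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing 16S OTU count tables from larval rearing
    experiments with frass, whole-caterpillar and plant samples. Provides an
    OTU-table container built on SummarizedExperiment with taxonomic filters
    and seeded rarefaction; chord-transform PCA, Bray-Curtis PCoA, Hill-number
    diversity and UPGMA clustering; Gibbs and Metropolis samplers for Bayesian
    group, linear and logistic models with DIC, Gelman-Rubin and effective
    sample size diagnostics; closed-form multinomial-Dirichlet differential
    relative-abundance models with posterior-predictive RMSE model comparison;
    random-forest sample classification; a synthetic-data generator that
    emulates a two-population, two-host-plant rearing design with known
    ground truth; and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    ape,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Microbiome, Bayesian, Classification, Clustering
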