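Package: pgxStrat
Title: Group-Stratified Pharmacogenomic Variation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing group-stratified pharmacogenomic variation in
    diverse cohorts. Simulates multi-group genotype cohorts under a
    Balding-Nichols allele-frequency divergence model with admixture, computes
    per-group alternate/effect allele frequencies from diploid dosage data,
    fits genotype principal component analyses with per-variant allele
    weights, ranks group-divergent variants by allele-weight magnitude,
    predicts group membership from principal component features with
    cross-validated classifiers, and computes predicted excess adverse drug
    reactions per 1000 treated between groups under dominant and recessive
    toxicity-allele effect models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    VariantAnnotation,
    randomForest,
    e1071,
    class,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
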