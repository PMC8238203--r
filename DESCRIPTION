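Package: netsnp
Title: Neural-Network Scoring of Genetic Variants in Case/Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores individual genetic variants by how much artificially
    assigning a genotype (homozygous minor allele) to every holdout individual
    shifts the output of a trained case/control pattern-recognition network.
    Provides sparse genotype storage from VCF, cohort filtering and
    case:control-balanced splitting, per-SNP Fisher's exact allele-count
    association with shuffled-label Q-Q calibration, a scaled conjugate
    gradient neural-network trainer, the target-SNP scoring engine with a
    random-SNP significance band, constructed-disease (negative control)
    simulation, a synthetic rare-variant cohort generator with known ground
    truth, and burden-based validation against age of diagnosis and
    neuropathology stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    tools,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
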