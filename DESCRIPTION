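Package: hallmarkTasks
Title: Transcription-Translation Decoupling Across Cancer Hallmark Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the decoupling of transcription and translation in
    cancer cell lines from paired mRNA and protein abundance profiles.
    Computes same-cell versus cross-cell mRNA-protein concordance, preranked
    gene-set enrichment of the ten cancer hallmark tasks with
    permutation-based normalized enrichment scores and false-discovery
    control, the difference- and range-of-enrichment statistics with a
    bootstrap difference-of-means null, and their association with nominal
    division rates and drug growth inhibition. Includes a synthetic-cohort
    generator that emulates the statistical structure of paired LINCS-style
    profiles for calibration and parameter-recovery testing, plus a
    single-command pipeline with TSV/GMT/JSON interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
biocViews: GeneSetEnrichment, Proteomics, Transcriptomics, Software
RoxygenNote: 7.3.3
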