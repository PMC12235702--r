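Package: synprot
Title: Drug-Combination Synergy Scoring and TMT Proteomics Differential
    Expression with Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for combination drug-treatment studies that
    pairs dose-response synergy scoring with downstream quantitative
    proteomics. Computes delta synergy scores on dose-response viability
    matrices under an independent-action expectation, performs two-batch
    TMT (tandem mass tag) differential-expression analysis with Student
    t-tests and fold-change thresholds, runs hypergeometric
    over-representation and preranked gene set enrichment analysis with a
    permutation null, and provides principal-component quality control.
    A synthetic-data generator plants known synergy, known differential
    proteins, and known enriched gene sets so every stage is verifiable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
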