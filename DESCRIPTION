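Package: regulonSets
Title: Set-Level Classification of Prokaryotic Expression Data with
    Regulatory Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds gene-set families from prokaryotic operon,
    transcription-unit and transcription-factor regulatory annotation
    (operons, transcription units, continuous operon subsequences, TF
    target sets, regulons and strict regulons, plus size-preserving
    randomized controls), aggregates gene expression over the sets, and
    evaluates set-level phenotype classifiers against gene-level baselines
    with leave-one-out cross-validated support vector machines, Friedman
    rank sums and one-sided paired Wilcoxon comparisons. Includes a
    combinatorially weighted within-set correlation sampler and a seeded
    synthetic genome and expression generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
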