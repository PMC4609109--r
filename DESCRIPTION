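Package: ThermAdapt
Title: Transcriptome Evolution Analysis for Thermally Adapted Escherichia coli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of bulk expression matrices from thermal
    adaptive-evolution experiments: global median normalization, replicate
    averaging, hierarchical clustering of condition profiles, principal
    component analysis with loading-based gene selection, gene-set
    enrichment (exact binomial over-representation and a ranked
    running-sum statistic with permutation significance), and a
    decomposition of heat-shock- and mutation-induced transcriptional
    change that quantifies negative epistasis as one minus the slope of
    simultaneous on additive expression change. Includes a synthetic-data
    generator with known ground truth (cumulative genotype effects,
    a planted heat-shock regulon, genotype/temperature anti-correlation,
    and a multiplicative epistatic cancellation) for end-to-end testing
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
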