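Package: reporterpa
Title: Reporter Pathway Analysis of Transcriptome Data on Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores metabolic pathways for coordinated transcriptional change
    by aggregating gene-level Z-scores over neighborhoods of a genome-scale
    metabolic network. Implements a metabolite-centric reporter pathway
    statistic, which credits a pathway with every reaction that consumes or
    produces its metabolites (including reactions catalogued under other
    pathways), alongside the classical reaction-centric variant that only uses
    a pathway's own member reactions. Both statistics are standardized against
    Monte Carlo background distributions of random same-size gene sets.
    Includes directional (up/down) analyses, Benjamini-Hochberg adjustment,
    parsers for BioCyc SmartTables-style network exports, and a synthetic
    network and expression generator with planted perturbations for
    validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
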