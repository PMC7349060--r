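Package: yieldvar
Title: Yield Stability Regression and GBS Variant Analysis for Landrace Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting high- and stable-yielding crop genotypes from
    multi-environment trials using environment-index stability regression
    (Finlay-Wilkinson / Eberhart-Russell style), together with summarization of
    a multi-sample genotyping-by-sequencing variant panel: missingness and
    depth filtering, private-marker counting, identity-by-state distances,
    SnpEff-style variant effect classification, and detection of putative
    wild-relative introgressions from InDel flanking-sequence alignment.
    Includes a synthetic-data generator (field trials, toy genomes with gene
    models, variant panels, diverged wild genomes) with ground-truth records so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
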