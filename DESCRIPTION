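Package: wgdexpr
Title: Time-Course Expression Profiling and Ohnolog Retention Analysis
    for Paleopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse genome-wide time-course expression data from
    organisms shaped by successive whole genome duplications (WGD), such as
    the ciliate Paramecium tetraurelia. Provides probe-level microarray
    preprocessing (normal+exponential background correction, quantile
    normalization, median-of-probes gene summarization, density and
    replicate quality control), nuclear-morphology staging of autogamy
    samples, staged differential expression with empirical-Bayes moderation
    and fold-change-threshold (TREAT-style) testing, complete-linkage
    co-expression clustering with archetype naming, permutation gene-set
    enrichment, and ohnolog bookkeeping across nested WGDs: retention rates,
    cluster-concordance classification and an upper bound on the
    subfunctionalization rate. A synthetic paleopolyploid data generator
    with full ground truth (retention, expression archetypes,
    subfunctionalization, pseudogenization, cross-hybridizing probes) makes
    every stage testable without access to the original arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    limma,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
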