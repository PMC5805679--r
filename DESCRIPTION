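Package: ripcor
Title: RIP-Seq Enrichment, Binding-Site Scanning and RNA-Protein Correlation
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for RNA immunoprecipitation sequencing (RIP-seq)
    of RNA-binding proteins in erythroid cells. Implements negative-binomial
    enrichment calling on pulldown count matrices (median-of-ratios size
    factors, Wald and likelihood-ratio tests with Benjamini-Hochberg
    correction), consensus binding-site scanning over annotated transcript
    regions (5'UTR/CDS/3'UTR), label-free proteomics processing (detection
    filtering, reference scaling, left-censored downshifted-normal imputation,
    S0-moderated t/ANOVA statistics, in-silico tryptic digestion), RNA-protein
    integration (RPKM, Z-scores, per-gene Pearson and per-sample Spearman
    correlations, set overlaps, hypergeometric over-representation analysis),
    and a synthetic-data generator with exported ground truth for recovery
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
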