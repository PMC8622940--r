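Package: medipdmr
Title: Differential Methylation Analysis for meDIP-Seq Consensus Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for region-level differential DNA methylation analysis
    of meDIP-seq experiments with a three-group (exposed, handling-control,
    control) by two-sex design. Builds consensus regions from per-sample peak
    calls with a minimum-support filter, counts sequenced fragments per region,
    normalizes to log2 RPKM with empirical-Bayes batch adjustment that protects
    treatment and sex effects, fits moderated linear models for sex-concordant
    and sex-stratified tiers, classifies differentially methylated regions into
    exposure-specific, control-specific and shared categories with sex-tier
    reassignment, tests direction bias with Monte-Carlo chi-squared tests,
    measures genomic-feature enrichment against permutation nulls, and scores
    gene-set enrichment by gene-score resampling. Includes a synthetic-data
    generator reproducing the full study design so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    sva,
    jsonlite
Config/testthat/edition: 3
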