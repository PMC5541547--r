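Package: zdosage
Title: Sex-Chromosome Dosage Compensation Analysis for ZW Systems
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistics and tooling for assessing sex-chromosome dosage
    compensation from bulk RNA-seq expression matrices in female-heterogametic
    (ZW) species such as the silkworm Bombyx mori. Computes autosome-relative
    Z-linked expression (Z:A ratios, mean- and median-based), per-gene
    male:female expression ratios and their class-level summaries, bootstrap
    percentile confidence intervals for the median Z:A ratio, Mann-Whitney
    rank-sum comparisons, quartile-stratified contrasts (independent and
    max-of-pair binning), TMM between-sample normalization, FPKM derivation,
    and Z-linked expression profile export. A negative-binomial count
    simulator with known ground truth makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Normalization, Sequencing
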