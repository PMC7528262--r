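Package: cnvpop
Title: Comparative Copy-Number-Variation Analysis Between Cattle Subspecies
Version: 0.1.0
Authors@R: person("CNV", "Pipeline Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Integrates per-animal CNV calls from a boundary-resolution
    structural-variant caller (split-read/paired-end, VCF) and a read-depth
    caller (CNVnator-style text) into confident calls, merges them into CNV
    regions (CNVRs), dissects CNVRs into boundary-consistent segments,
    genotypes every animal at every segment into five copy-number classes
    (0, 1, 2, 3, >=4), and computes a genotype-class F_ST per segment to
    rank lineage-differential CNV segments between two populations (e.g.
    taurine versus indicine cattle). Also provides the accompanying genomic
    summaries (gene/exon overlap, feature-class enrichment, 1-Mb window
    density and CNV clusters, breed/subspecies sharing, subspecies-specific
    sequence filtering) and a two-population synthetic-data generator with
    known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    BiocGenerics,
    SummarizedExperiment,
    jsonlite
Config/testthat/edition: 3
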