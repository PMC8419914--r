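Package: fstsweep
Title: Windowed Fst Selective-Sweep Scanning with Variant QC, PCA and
    Differential Expression Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable divergence-scan pipeline for two-population
    resequencing studies (e.g. wild versus domesticated lineages): VCF hard
    filtering with SNP-cluster and missing-rate rules, per-SNP Weir-Cockerham
    (1984) Fst with sliding-window aggregation and top-percentile candidate
    region extraction, gene annotation of candidate regions, genotype PCA with
    allele-frequency scaling, FPKM standardization and a negative-binomial
    Wald test for differential expression with Benjamini-Hochberg correction,
    and the intersection of sweep candidate genes with differentially
    expressed genes plus a database-free hypergeometric over-representation
    test.  Includes a Balding-Nichols genotype simulator and a
    negative-binomial count simulator so every stage can be exercised against
    a known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
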