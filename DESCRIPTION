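Package: vcbench
Title: Set-Theory Benchmarking of Variant Calling Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Benchmarks variant caller output against a gold-standard call
    set using an explicit set-theory model. Given a truth VCF, one or more
    query VCFs, a target-capture BED and a high-confidence-region BED, the
    package builds the three variant sets A (truth in target regions),
    B (query in target regions) and C (query in high-confidence regions),
    derives six discrete categories (TP, FP, FN, NAC, O, I) by set
    operations, and computes continuous metrics (recall, precision,
    Frac_NA, F1), summary statistics (Ts/Tv ratio, functional-class
    counts, per-chromosome counts, variant rate), multi-caller Venn
    concordance, and ROC/AUC comparisons with significance tests. A
    seeded synthetic-fixture generator emits complete benchmark bundles
    (VCF + BED) with exactly controlled category counts so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
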