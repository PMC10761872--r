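Package: migratome
Title: Regulatory Divergence and Migratory-State Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for studying the regulatory basis of
    seasonal migration across a songbird hybrid zone. Provides
    negative-binomial differential expression across migratory states,
    subspecies and their interaction; allele-specific expression in
    hybrids to separate cis- from trans-regulatory divergence, overall
    and in the genotype-by-environment contrast; transgressive
    (mis)expression calling in hybrids; windowed population-genetic
    statistics (pi, dXY, FST) at conserved non-coding elements and
    introns with a mixed-model association against differential
    expression; nightly migratory-restlessness scoring from activity
    traces; exact chance-overlap statistics for gene lists; and a
    seeded synthetic-data generator that emulates every input with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
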