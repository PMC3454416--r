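Package: bivalentEnrich
Title: Enrichment of Age-Associated Differentially Methylated Sites in
    Bivalent Chromatin Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests whether age-associated differentially methylated CpG
    sites from promoter-biased methylation arrays fall inside bivalent
    chromatin (H3K4me3/H3K27me3) gene regions more often than expected.
    Implements probe-set partitioning by age group and methylation
    direction, a global enrichment ratio with a track-randomization
    Monte Carlo null that preserves segment lengths and inter-segment
    gaps, a case-control label-permutation test for hyper- versus
    hypo-methylated sites, gene annotation of overlapping probes, and a
    seeded synthetic-data generator with planted enrichment for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
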