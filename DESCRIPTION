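Package: crossvar
Title: Cross-Platform SNV Concordance, Chip Comparison and Callability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares single-nucleotide variant (SNV) call sets produced by
    two sequencing platforms from the same individual: three-way concordance
    classification (concordant, discordant, platform-specific),
    zygosity-stratified genotype concordance against SNP-chip calls, a
    stringent pileup-based filter for highly confident heterozygous calls,
    per-base callability classification (callable, poor mapping quality,
    low coverage, no coverage) with multi-platform track merging, and
    summary reports with chi-square/odds-ratio comparisons. Includes a
    seeded diploid-genome simulator (repeat regions, platform-specific
    dropout, depth-dependent heterozygous undercalling, chip genotyping
    error) so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
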