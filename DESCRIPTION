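Package: popsweep
Title: Selection-Signature Scans from Two-Population SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects genomic signatures of selection by comparing two
    populations genotyped on a SNP array. Implements genotype quality
    control with heterozygosity-based inbreeding filtering, sliding-window
    runs-of-homozygosity (ROH) detection in three length classes with
    population consensus regions, per-SNP Nei fixation-index scans averaged
    over 500-kb windows, and cross-population extended haplotype
    homozygosity (XP-EHH) with genome-wide standardization and
    false-discovery-rate control. Candidate regions flagged by both
    differentiation tests are intersected and annotated against local
    gene or QTL interval files. A Balding-Nichols two-population simulator
    with sweep and autozygosity planting operators provides fully
    controllable synthetic panels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
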