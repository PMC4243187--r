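Package: ldphase
Title: Linkage Disequilibrium Decay, Phase Persistence and Haplotype Blocks
    from Phased SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising linkage disequilibrium (LD) in
    livestock SNP panels from phased haplotypes: genotype and sample
    quality control (call rate, exact Hardy-Weinberg test, minor allele
    frequency), two-locus LD statistics (D, D', r-squared, signed r) with
    likelihood-based confidence intervals on D', distance-binned LD-decay
    profiles, persistence of LD phase between two genetic groups as the
    per-bin correlation of signed r, and Gabriel-style
    confidence-interval haplotype-block partitioning with per-chromosome
    summaries. Includes a forward Wright-Fisher simulator of a composite
    (admixed) population split into two genetic groups, so the whole
    pipeline can be exercised on synthetic data with realistic LD decay
    and cross-group phase agreement. Reads phased VCF and PLINK text
    (PED/MAP) input and writes TSV/BED result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
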