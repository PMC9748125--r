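Package: compsel
Title: Composite Selection Signal Scans with Expression Integration and
    Association Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects selective sweeps between a selected and a reference
    cohort by combining per-SNP selection statistics (Hudson's Fst, the
    change in selected allele frequency, and cross-population extended
    haplotype homozygosity) into a composite selection signal (CSS) via
    inverse-normal transformation of genome-wide fractional ranks, with
    window smoothing and top-percentile cluster calling. Integrates scan
    SNPs with differentially expressed gene sets through a matched-size
    resampling null with empirical-null local false discovery rates,
    prioritises protein-coding variants in candidate regions, and
    validates candidate SNPs with allelic case-control association under
    Bonferroni control. Includes a two-population haplotype simulator
    (Balding-Nichols divergence, Markov copying for linkage
    disequilibrium, planted hard sweeps) so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
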