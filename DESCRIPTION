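Package: sweepscanr
Title: Selective-Sweep Scanning with Smoothed FST, Diversity-Ratio Z
    Scores, and XP-EHH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-statistic selective-sweep scan for two-population
    phased SNP data: per-SNP Weir-Cockerham FST with Gaussian-kernel
    smoothing and an escalating bootstrap-resampling outlier null,
    log2 nucleotide-diversity-ratio Z scores, and cross-population
    extended haplotype homozygosity (XP-EHH) with genome-wide
    normalization. Candidate regions are called where all three tests
    agree. Includes a CpG-site intactness test (exact 2x2 enumeration)
    and a methylation fold-change outlier screen for detecting
    selection on differentially methylated haplotypes, plus a
    deterministic two-population haplotype simulator with known hard
    sweeps for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    vcfR,
    IRanges,
    Biostrings,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
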