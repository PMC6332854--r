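Package: haploscan
Title: Sliding-Window Haplotype Genome-Wide Association for Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Variable-sized sliding-window haplotype genome-wide association
    analysis for quantitative traits in livestock populations. Builds
    overlapping windows of consecutive phased SNPs, codes per-allele diplotype
    dosages, fits a linear mixed model with a standardized-genotype genomic
    relationship matrix, converts per-allele substitution effects into
    additive genetic variances for multi-allelic haplotype loci, calls
    significant loci against Bonferroni-corrected gamma-distribution variance
    thresholds (with cubic and Brody smoothing of the gamma parameters over
    haplotype allele counts), summarizes linkage disequilibrium decay, and
    merges significant windows into QTL regions. Includes a founder-copying
    simulator of phased genotypes and phenotypes with contemporary-group and
    age fixed effects and a polygenic background, so the whole pipeline can be
    exercised and calibrated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    S4Vectors,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite
Config/testthat/edition: 3
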