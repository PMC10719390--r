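Package: zwks
Title: Sex-Specific K-mer Screening and Diagnostics for ZW Chromosome
    Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering a poorly differentiated W chromosome
    from mixed male/female sequencing data by sex-specific k-mer
    screening. Implements exact canonical k-mer counting and set algebra
    (filter, union-sum, intersect, difference), derivation of
    female-specific k-mers from resequencing panels, partitioning of long
    reads by k-mer membership, a unique-anchor read mapper with windowed
    log2(M/F) depth-ratio and heterozygous-SNP diagnostics, MinHash
    sketch identity for Z-candidate detection, k-mer based assembly
    quality (QV) estimation, and a seeded synthetic ZW genome and read
    simulator with full truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomeInfoDb,
    jsonlite,
    Rcpp,
    stats,
    SummarizedExperiment,
    utils,
    VariantAnnotation,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
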