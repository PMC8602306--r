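Package: pegscreen
Title: Hit Calling for FACS-Sorted CRISPR Screens and Imprinted-DMR
    Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled CRISPR/Cas9 loss-of-function screens read out
    by FACS sorting of a reporter-positive subpopulation, as used to find
    repressors of imprinted paternally expressed genes in haploid
    parthenogenetic human embryonic stem cells. Counts sgRNA spacers in
    amplicon reads, normalizes counts to reads per million, computes
    per-sgRNA log2 fold changes between sorted and unsorted samples per
    immunostaining experiment, aggregates them to a robust per-gene score
    (outlier-trimmed median, centered on the library median), attaches a
    two-sample Kolmogorov-Smirnov enrichment p-value, and calls candidate
    genes through a four-filter rule including a negative-sort subtraction
    and an expression (TPM) gate. A companion module aggregates CpG-level
    bisulfite methylation to differentially methylated region (DMR) means,
    filters informative maternal/paternal DMRs, computes delta methylation
    between treatments, and classifies the demethylation response of
    paternally expressed genes. A synthetic-data generator produces every
    input with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
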