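Package: chromTE
Title: Chromosome-Scale Organization of Transposable Elements, Diversity
    and Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistics for the organization of transposable elements (TEs)
    along chromosomes and their relationship with chromosome size, motivated
    by the lepidopteran pattern of denser TEs on smaller chromosomes.
    Provides RepeatMasker annotation input/output with divergence-based age
    classes, 100-kb windowed repeat/GC/coding-sequence densities with
    percentile-bootstrap confidence intervals, adjacent inter-TE spacing
    statistics and the young/old spacing ratio, Spearman correlation with
    Benjamini-Hochberg correction and multiple linear regression against
    chromosome size, missing-data-aware nucleotide diversity from all-sites
    VCFs with 0-fold/4-fold codon-degeneracy site classification, folded
    site-frequency spectra with gamma-distributed fitness-effect estimation
    under a Poisson random field model, and a synthetic genome and
    population simulator (size-dependent TE insertion and NAHR-like
    deletion of inter-TE sequence) with full ground-truth records for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
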