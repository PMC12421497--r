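Package: fastz
Title: Fast-Z and Large-Z Population Genomics for ZW Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate fast-Z and large-Z effects from population-level
    variant data in ZW sex-determination systems such as birds. Implements
    sex-aware genotype and site filtering with a callable-site ledger,
    outgroup-based allele polarization and ancestral-sequence reconstruction,
    nucleotide diversity and Z:A effective-population-size ratios with
    male-biased mutation correction and bootstrap confidence intervals,
    harmonic-mean Ne ratios from demographic trajectories, degeneracy
    classification and GC-conservative selection summaries (piN/piS, dN/dS,
    unfolded site frequency spectra), windowed Weir-Cockerham FST with
    Savitzky-Golay peak calling, the population branch statistic, selective
    sweep post-processing, fixed-difference and functional-overlap analyses
    with Fisher exact Z-versus-autosome enrichment, and Patterson's D and f_d
    introgression statistics with block jackknife inference. Includes a
    ZW-aware structured-coalescent data generator so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stringr,
    signal,
    vcfR,
    IRanges,
    Biostrings,
    generics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    broom,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
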