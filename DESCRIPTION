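Package: purgescan
Title: Genetic Load, Purging and Selective-Sweep Scans for Multi-Population SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic toolkit for detecting purging of recessive
    deleterious variation in small, inbred plant populations. Provides
    codon-aware functional site annotation from FASTA/GFF3, outgroup-based
    ancestral-allele polarization, a per-individual genetic-load proxy
    (derived deleterious over derived four-fold-degenerate allele dosage),
    class-stratified unfolded site-frequency spectra with hypergeometric
    projection, windowed nucleotide diversity and Weir-Cockerham FST scans,
    PLINK-style runs-of-homozygosity detection, and outlier-window sweep
    candidate intersection. A forward-time Wright-Fisher simulator with
    selection, dominance, selfing and demography generates complete input
    bundles (VCF, FASTA, GFF3, outgroup and clade tables) so the whole
    pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
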