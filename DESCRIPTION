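Package: norpop
Title: Population Genomics of Northern Native Cattle Breeds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-variant-calling population genomics toolkit modelled on
    whole-genome resequencing studies of small native cattle populations:
    GATK-style hard filtering of SNP and indel records, per-breed variant
    accounting (shared/private sets, Ts/Tv, het/hom, novelty against a
    known-sites catalogue, array concordance), functional annotation of
    variants against a gene model, nucleotide diversity and Watterson's
    theta, folded one- and two-population site frequency spectra,
    SweepFinder-style composite likelihood ratio scans for selective
    sweeps with empirical outlier calling and window-based gene
    annotation, Fisher exact GO term enrichment with Bonferroni
    correction, and maximum-likelihood inference of an
    ancestral-size-change-plus-split demographic model from the folded
    joint spectrum. Includes a coalescent simulator of the same model
    family so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
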