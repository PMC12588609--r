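Package: csdmapr
Title: Homozygosity Mapping of Complementary Sex Determination Loci in
    Clonal Haplodiploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps candidate complementary sex determination (CSD) loci in
    clonal (automictically parthenogenetic) haplodiploid lineages from
    multi-sample genotype data. Implements the per-SNP CSD index with a
    colony-stratified permutation null and Benjamini-Hochberg false
    discovery rate control, site-level genotype-quality filters (haploid
    heterozygosity and allelic-depth screens), ancestral-heterozygosity
    calling within clonal lines, rule-based loss-of-heterozygosity (LOH)
    segmentation with cross-sample intersection and copy-number
    classification from normalized read depth, and windowed nucleotide
    diversity for balancing-selection checks. A forward simulator of
    central-fusion automixis with a planted CSD locus generates complete
    synthetic cohorts (VCF, metadata, truth tracts) so that every stage of
    the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
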