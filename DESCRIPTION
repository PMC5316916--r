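Package: wbatk
Title: Analysis Toolkit for High-Density Wheat SNP Array Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for working with genotype matrices from high-density SNP
    genotyping arrays in hexaploid bread wheat (Triticum aestivum). Covers
    informative-marker panel selection (one SNP per contig by mapping status,
    codominance and polymorphic information content), two-point linkage map
    construction from biparental doubled-haploid, recombinant-inbred and
    single-seed-descent populations (missing-data filtering, segregation
    binning, linkage grouping, seriation ordering, segregation-distortion
    chi-square scans and consensus map merging), germplasm diversity
    statistics (allele frequencies, expected heterozygosity, rarity index,
    Weir-Cockerham FST, shared and unique polymorphisms, identity-by-state
    similarity and principal coordinate analysis), and copy-number profiling
    from probe signal intensities (Log2R ratios against a reference panel
    with loss/gain segment calling). A synthetic-data module simulates
    biparental populations under Haldane recombination, structured
    collections under the Balding-Nichols model, and intensity matrices with
    copy-number events, so every analysis is testable without array data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
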