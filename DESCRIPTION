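Package: polygbs
Title: Reference-Free Genotyping-by-Sequencing for Polyploid Mapping Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale genotyping-by-sequencing (GBS) toolkit for species
    without a reference genome, with first-class support for allopolyploids and
    paired-end reads. Builds GBS reference tags de novo from paired-end reads
    (overlap merging or artificial joining, within-sample stack clustering and
    across-sample consensus clustering), scores F2 genotypes from allelic read
    depths with explicit ambiguity codes, consolidates and deduplicates genotype
    matrices, constructs two-point linkage maps with Kosambi distances and
    cosegregation bins, and assigns linkage groups to subgenomes using reads from
    a diploid progenitor, including translocation-breakpoint and dosage
    detection. Includes a fully deterministic synthetic-data generator for an
    allotetraploid F2 population (restriction digest, meiosis, read simulation)
    so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
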