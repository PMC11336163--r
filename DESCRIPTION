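Package: poplayers
Title: Layered Population-Genomic Structure from RAD-Seq SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for peeling back layers of genomic structure in RAD-seq
    SNP datasets of Arctic gadids and similar systems: screening for
    interspecific hybrids and mito-nuclear discordance, detecting and
    karyotyping large chromosomal inversions from allele-loading and
    linkage-disequilibrium aggregation, locating sex-linked regions,
    partitioning outlier from neutral loci, and quantifying neutral
    population structure with FST, ancestry, and discriminant analyses.
    Includes a fully parameterised synthetic-data generator so the whole
    pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    vcfR,
    MASS,
    mclust,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
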