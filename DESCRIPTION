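Package: triadbias
Title: Homoeolog Expression Bias and Genome Features in Phased Triploid Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing homoeolog expression bias in triploid,
    haplotype-resolved genome assemblies. Builds 1:1:1 allele triads across
    three haploid assemblies from reciprocal-best protein hits, computes TPM
    and per-triad relative (ternary) expression, classifies triads into seven
    bias groups (balanced, dominant and suppressed per haplotype), compares
    Nei-Gojobori Ka/Ks across bias categories, detects telomere tracts,
    centromeric tandem arrays and NLR locus clusters, and ships a synthetic
    triploid-data generator with a ground-truth table so the whole pipeline is
    testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
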