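Package: paralogtrap
Title: Detecting Pseudogene Misalignment Artefacts in Somatic Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether candidate somatic single-nucleotide variants
    at a gene locus are misalignment artefacts caused by reads that truly
    originate from a homologous pseudogene carrying a common-SNP haplotype.
    Implements exact Smith-Waterman local alignment with affine gaps, homology
    envelope derivation and cross-locus position projection, error-free read
    simulation with tumor (FFPE, short) versus normal (blood, long)
    read-length models, multi-locus alignment with mapping-ambiguity
    classification, variant calling from alignment mismatches, dbSNP-style
    catalogue annotation with minor allele frequencies, linkage-disequilibrium
    statistics (D, D', r-squared) from phased haplotype panels, the
    two-criterion artefact decision rule with a germline leak-through risk
    model, and a synthetic gene/pseudogene data generator so the whole
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
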