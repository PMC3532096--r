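Package: bdsmap
Title: Birth Date Selection Mapping for Temporally Stratified Genotype Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects loci under ongoing polygenic selection by treating birth
    date as the dependent variable in genome-wide mixed models. Provides
    genotype and pedigree input with quality-control filters, VanRaden genomic
    relationship and Balding-Nichols kinship matrices, single-kernel REML,
    GBLUP with allele-substitution-effect backsolving, EMMAX-style two-stage
    association scans, a BayesC-pi Gibbs sampler, pedigree and genomic
    inbreeding with effective-population-size estimation, a per-SNP
    drift-versus-selection test, generalized-least-squares reconstruction of
    relative selection intensities, and a forward-in-time simulator of
    overlapping-generation pedigreed populations under multi-trait truncation
    selection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
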