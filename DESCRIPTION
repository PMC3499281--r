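Package: rhmapper
Title: Radiation Hybrid Map Construction, Validation and Marker Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds high-density radiation hybrid (RH) maps from SNP-array
    genotyping of hybrid clone panels and uses them to validate and extend a
    draft genome assembly. Covers intensity-based presence/absence genotype
    calling with control filters, two-point linkage and LOD-based group
    construction, a haploid hidden-Markov multipoint likelihood with
    EM-fitted breakage and retention parameters, comparative ordering
    against an assembly prior with 2-opt/Or-opt search, MCMC sampling of
    marker orders and extraction of robust (framework) maps, crossover
    counting in half-sib families for genetic validation of marker orders,
    chi-square similarity placement of unmapped SNPs and scaffolds, and an
    analytic model of RH panel resolution. A synthetic-data generator with
    known ground truth emulates the breakage-retention process, array
    intensities, half-sib pedigrees and assembly ordering errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
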