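Package: aimsel
Title: Ancestry-Informative Marker Panels by Stepwise Flexible Discriminant Analysis
Version: 1.0.0
Authors@R: person("aimsel", "developers", email = "aimsel@example.org", role = c("aut", "cre"))
Description: Selects minimal panels of ancestry-informative markers from SNP
    genotypes and/or gene-expression intensities. Implements flexible
    discriminant analysis by optimal scoring with a linear basis, forward
    stepwise marker selection driven by training accuracy with a
    within/between sum-of-squares tie-break, stratified k-fold
    cross-validation with candidate-model consistency statistics, the
    marker quality-control chain (call rate, minor allele frequency,
    permutation-based Hardy-Weinberg testing with false-discovery-rate
    adjustment, sex-chromosome and probe-annotation filters), a
    population-structure simulator with known ground truth, and tabular
    reports with optional plots plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
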