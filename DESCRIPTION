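Package: asmsv
Title: Structural Variant Discovery, Genotyping and Characterization from
    De Novo Assembly Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers structural variants and novel sequence from pairwise
    alignments of de novo genome assemblies against a reference (LAST-dialect
    MAF), genotypes them across a population with a linear-constrained
    three-state Gaussian mixture model fitted by expectation-maximization on
    per-allele read intensities, recalibrates variant quality with
    positive/negative Bayesian Gaussian mixtures over nine technical features,
    filters by the inbreeding coefficient, and annotates ancestral state
    (against outgroup genomes) and formation mechanism (NAHR, NHR, TEI, VNTR,
    CCC) from breakpoint and repeat structure. Includes a deterministic
    synthetic-data generator producing every input with known ground truth,
    and emits standards-compliant VCF plus summary reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    Biostrings,
    IRanges,
    mclust,
    pROC,
    MASS,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
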