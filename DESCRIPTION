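Package: tcrsplit
Title: Distance-Controlled Data Splits for TCR-Peptide Binding Benchmarks
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building out-of-distribution benchmarks for T cell
    receptor (TCR) - peptide binding predictors. Reads VDJdb-style interaction
    tables, generates shuffled negative pairs, computes pairwise peptide
    distances (Levenshtein edit distance, BLOSUM global-alignment distance,
    and C-alpha RMSD on peptide structures), and partitions records into
    train/validation/test sets with the Distance Split algorithm, which
    constrains test and validation peptides to a percentile band of the
    aggregated peptide-peptide distance distribution while keeping peptide
    sets disjoint across splits. Random Split and Hard Split baselines, a
    synthetic fixture generator, and a small evaluation harness with
    reference predictors are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
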