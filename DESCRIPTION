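Package: plexbridge
Title: Bridge-Anchored Normalization and Analysis of Multi-Batch TMT Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for multiplexed tandem-mass-tag (TMT)
    proteomics studies that span several MS sets and acquisition batches.
    Provides target-decoy false-discovery-rate filtering of peptide-spectrum
    matches with a linear discriminant score, parsimony protein inference,
    quantification filters, bench quality-control statistics (missed
    cleavage, labeling efficiency, ratio check), bridge-sample normalization
    within and across sets with protein rollup and 0-100 scaling,
    batch-effect diagnostics (PCA, silhouette scores, replicate
    correlations, set-intersection accounting), and per-protein linear
    models of drug response with a receptor-status covariate. A
    synthetic-data generator emulating an 8-set, 2-batch, bridge-anchored
    cell-line panel makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
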