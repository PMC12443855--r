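Package: dormclass
Title: Dormancy-Stage Classification from Whole-Genome Bisulfite
    Sequencing Methylation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying bud dormancy stages (paradormancy,
    endodormancy, ecodormancy) of temperate fruit trees from per-cytosine
    bisulfite-sequencing methylation reports.  Implements coverage and
    presence filtering of cytosines, gap-based clustering of cytosines into
    methylated regions, consensus feature selection by intersecting
    non-zero importance across random-forest impurity, gradient-boosting
    gain and exact tree Shapley attributions of both models, repeated
    stratified cross-validated evaluation with paired significance testing
    of the selection benefit, and genomic annotation of selected features
    against genes, promoters, transposable elements and quantitative trait
    loci.  A seeded synthetic-methylome generator with planted
    stage-informative loci and cultivar confounding makes the whole
    pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    randomForest,
    xgboost,
    pROC,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
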