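Package: pbpclust
Title: Subquadratic Hierarchical Clustering of Amplicon Sequences into OTUs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Agglomerative hierarchical clustering of amplicon sequencing reads
    (16S rRNA and similar marker genes) into operational taxonomic units in
    subquadratic time. Sequences and cluster consensus profiles are indexed in
    a pseudo-metric based partitioning (PBP) tree, an ordered equal-depth
    hyper-sphere hierarchy supporting near-constant insertion and deletion and
    sublinear branch-and-bound nearest-neighbour search. Clusters are merged
    by a multi-point mutual-nearest-neighbour criterion with delayed
    nearest-neighbour updating, reproducing exact sequential hierarchical
    clustering while exposing batch parallelism across replicated worker
    trees. Includes FASTA preprocessing (dereplication, length and primer
    filters), dendrogram cutting at arbitrary distance thresholds, alpha
    diversity estimators (Chao1, ACE, rarefaction), a synthetic amplicon read
    simulator with ground-truth labels, normalized mutual information
    evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    rlang,
    ggplot2,
    generics,
    parallel,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    dplyr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: C++17
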