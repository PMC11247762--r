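Package: sagmag
Title: Comparative Analysis of Single-Amplified and Metagenome-Assembled
    Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for judging how well two genome collections recovered
    from one microbial community -- single-amplified genomes (SAGs) and
    metagenome-assembled genomes (MAGs) -- represent that community.
    Implements compositional differential abundance (Dirichlet Monte
    Carlo with centered log-ratio transformation followed by the
    Games-Howell post-hoc test with a dual effect-size/p-value cutoff),
    rank-wise taxonomic richness and 95% ANI dereplication, greedy
    identity-threshold gene clustering with pangenome rarefaction
    (permutation and exact hypergeometric forms), KEGG-module gene-content
    standardization and comparison, consensus chimera calling from
    clade-separation and contamination evidence, 16S rRNA taxonomic
    conflict auditing, fragment-recruitment fraction comparison by the
    exact paired Wilcoxon signed-rank test, and a synthetic-data generator
    that emulates all pipeline inputs with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    igraph,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
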