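Package: ctenrich
Title: Cell-Type Enrichment of Age-Associated Gene Expression Rankings
Version: 0.1.0
Authors@R: person("ctenrich", "maintainers", email = "maintainers@ctenrich.org",
    role = c("aut", "cre"))
Description: Tests whether genes enriched in specific transcriptomic cell types
    are concentrated at either end of signed age-association gene rankings built
    from bulk-tissue expression studies. Derives cell-type enriched and
    non-specific gene sets from single-cell expression by z-score thresholding,
    scores them with threshold-free AUROC statistics, assesses significance with
    a cell-type label-permutation empirical null and an empirical min-p false
    discovery rate, and dissects cell-type sets by Gene Ontology groups. Includes
    a seeded synthetic-data generator emulating cell-type-structured single-cell
    matrices, age-association tables with planted directional shifts, ortholog
    maps and GO annotations, so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
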