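Package: miconet
Title: Co-Occurrence Communities of the Infant Gut Microbiome and Their
    Dietary and Autoimmune Associations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers compositionality-corrected Spearman co-occurrence
    networks of gut microbial genera, detects communities by Markov
    stability with plateau-based selection of the community number,
    stratifies subjects per community via UniFrac distances, k-medoids
    and the Calinski-Harabasz index, and tests stratified subgroups for
    associations with infant diet (breast-feeding, food complexity),
    time to islet-autoantibody seroconversion (Kaplan-Meier,
    proportional hazards), and the butyrate-pathway but/buk gene ratio
    from KEGG-ortholog tables. Includes a synthetic-cohort generator
    with ground-truth labels for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    survival,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
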