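Package: potevol
Title: Dating and Classifying Segmental Gene-Family Duplications
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Molecular-evolution toolkit for dating recent gene-family
    duplications and classifying paralogs from transposable-element
    signatures, built around the primate POTE family. Implements
    Jukes-Cantor and Kimura 2-parameter pairwise distances with analytic
    variances, neighbor-joining tree construction with bootstrap and
    interior-branch support, Tajima's relative rate test, calibrated
    molecular-clock dating (T = K/2R), a rule-based LINE-content
    classifier with a long-inverted-repeat detector, and a synthetic
    gene-family simulator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
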