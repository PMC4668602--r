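Package: fitchsearch
Title: Maximum-Parsimony Analysis of Discrete Morphological Characters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete maximum-parsimony workflow for discrete morphological
    character-taxon matrices: TNT and NEXUS matrix input/output, exact Fitch
    optimization of unordered multistate characters (with missing, inapplicable
    and polymorphic cells), heuristic tree search by random addition sequence
    and tree bisection-reconnection with positive and converse topological
    constraints, strict and agreement-subtree consensus, jackknife (GC) and
    Bremer clade support, MPR ancestral-state reconstruction with unambiguous
    synapomorphy mapping, and a seeded Mk-style simulator for generating test
    matrices with known histories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
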