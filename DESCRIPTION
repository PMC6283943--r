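Package: chronopsin
Title: Ancestral Gene Complements from Dated Gene and Species Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the minimal gene complement inherited at the base of stem
    lineages by comparing 95% credibility intervals on gene-duplication dates
    against credibility intervals on species divergence dates. Provides a data
    model and Newick/NEXUS input/output for dated phylogenies with credibility
    intervals and fossil tips, LCA (parsimony) reconciliation of gene trees
    onto species trees, canonical concatenated naming of ancestral paralogues,
    Dollo phylogenetic bracketing for extant clades, chromacy classification of
    visual-opsin complements, and a forward birth-death simulator with fossil
    sampling and emulated posterior node ages for end-to-end validation.
    Ships the published ecdysozoan visual-opsin duplication chain and
    divergence intervals as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
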