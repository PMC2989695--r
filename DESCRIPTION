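Package: cladegraph
Title: Node-Based and Stem-Based Phylogenetic Tree Models and Clade Semantics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the two standard graphical models of rooted
    phylogenies: node-based trees, in which taxa are vertices and edges are
    ancestry hypotheses, and stem-based (branch-based) trees, in which taxa
    are edges and vertices are speciation events. Provides the explicit
    relabeling algorithms that convert each model into the other, exhaustive
    enumeration of small labeled trees to certify that the two models are in
    one-to-one correspondence, the subtree correspondence between proper
    subtrees of a node tree and planted proper subtrees of its stem
    counterpart, and monophyly/paraphyly/polyphyly classification of taxon
    sets on either model. Includes a restricted Newick reader/writer with an
    explicit interpretation mode for each model, per-taxon character
    (apomorphy) annotation tables, seeded random-tree generation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    tibble,
    withr
Suggests:
    ape,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
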