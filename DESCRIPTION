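Package: dupliphy
Title: Gene-Duplication Screens and Reconciliation for Early Animal Branching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving deep phylogenetic branching order from gene
    duplications rather than single-copy orthologs. Provides a model-agnostic
    paralogy screen over Compara-style homology tables, draft gene-tree
    inference by neighbor-joining with seeded bootstrap, exhaustive rooting
    enumeration with LCA (last-common-ancestor) reconciliation and
    duplication/loss counting, duplication-timing classification of gene
    families against competing rooted species hypotheses (sponge-early versus
    ctenophore-early), and a fully seeded birth-death simulator of gene
    families with clade-specific rate asymmetry and compositional bias used
    to quantify the ortholog-miscalling artifact (false-positive gene loss
    and spurious rate and composition heterogeneity) that arises when gene
    trees from one world are forced into the other rooting model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
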