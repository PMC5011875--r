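Package: pharmselect
Title: Selective 3D Pharmacophores for Agonist/Antagonist Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds structure-based and ligand-based 3D pharmacophore models
    for nuclear-receptor ligand sets, refines them into class-selective models
    by an iterative screening protocol (omitted-feature probing and disabling
    of non-essential features), prunes redundant models, combines them into
    ensembles, and evaluates recall, specificity and Matthews correlation,
    including cross-receptor selectivity screening. Ships a synthetic
    benchmark generator that plants pharmacophoric archetypes in pseudo-ligand
    sets and geometrically complementary pseudo-complexes, so every step of
    the pipeline is testable against known ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    bio3d,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineOB
Config/testthat/edition: 3
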