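Package: qslattice
Title: Quaternary Structure Assemblies from Protein Crystal Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the biological assembly of a protein crystal structure.
    The crystal is represented as a periodic lattice graph (a crystal net)
    with chains as nodes and pairwise interfaces as translation-labelled
    edges. All topologically valid assemblies are enumerated under four
    formal rules (full coverage, uniform composition, isomorphism, closed
    point-group symmetry) by pruned power-set traversal over interface
    types, and ranked by a probabilistic score combining per-interface
    evolutionary (core-surface entropy Z-score) and geometric (core size)
    indicators through a logistic model. Includes buried-surface-area
    computation (Shrake-Rupley), interface-type clustering, entity
    contraction for heteromers, point-group detection, deterministic
    synthetic crystal and graph fixtures, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    Biostrings,
    withr
Config/testthat/edition: 3
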