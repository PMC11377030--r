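Package: treecollapse
Title: Taxonomy-Guided Collapsing of Phylogenetic Gene Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Collapses clades of large gene trees according to taxonomic
    information and user-chosen stop terms, preserving all within-species
    gene-duplication signal. Sibling clades are merged when their lowest
    common taxonomic ancestor lies at or below a stop term (for example a
    family or order name) and the merge would not place two sequences of
    the same species in one group. Collapsed nodes are named
    "<ancestor>_<index>_<count>" and a companion tab-delimited table maps
    every collapsed node to its member sequences. Includes Newick and
    NEXUS tree input, cladogram and phylogram output with weighted-average
    branch lengths, taxonomy flattening, a synthetic tree and taxonomy
    generator for testing, and a "collapse-tree" command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
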