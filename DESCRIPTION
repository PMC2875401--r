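Package: lgtree
Title: Tree-Based Detection of Lateral Gene Transfer in Microbial Genomes
Version: 1.0.0
Authors@R:
    person("Rory", "Mackenzie", email = "rmackenzie@example.org",
           role = c("aut", "cre"))
Description: Detects lateral gene transfer (LGT) from per-gene phylogenies
    using a bootstrap-gated tree-walk classifier and Fitch parsimony
    ancestral-state reconstruction to infer the donor clade and direction of
    transfer. Includes Kimura two-parameter distances, neighbor-joining tree
    construction with nonparametric bootstrap support, rooting utilities,
    compositional statistics (GC content, codon-usage correlation, pairwise
    percent identity), per-genus BLAST e-value profile matrices, seeded
    simulators with planted transfer events for validation, and a packaged
    machine-readable fixture of the fosmid gene table the method was
    developed on.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
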