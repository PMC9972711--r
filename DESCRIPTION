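Package: clonalmst
Title: B-Cell Lineage Tree Reconstruction by Abundance-Aware Minimum
    Spanning Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs B-cell receptor (BCR) IGH lineage trees from
    clonally related nucleotide sequences. Genotypes are collapsed with
    their cellular abundances, pairwise hamming distances on a multiple
    sequence alignment weight a genotype graph, and a bi-objective
    variant of Prim's minimum spanning tree algorithm (minimum edge
    weight first, maximum genotype abundance second) grows the rooted
    lineage tree from the inferred unmutated ancestor. Post-hoc editing
    inserts unobserved intermediate ancestors and performs
    cost-conserving depth-reducing moves. Includes exact tree-based and
    path-based graph edit distances, MRCA and COAR ancestral
    reconstruction distances for comparing lineage trees, and a
    branching-process somatic hypermutation simulator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
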