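Package: recombalign
Title: Recombination-Aware Alignment of Sequences to Variation Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact global alignment of query sequences against the
    distinguished paths of an acyclic variation graph, allowing at most one
    recombination: the alignment may switch from one path to another through
    a virtual arc, penalized by an affine function of a bubble-anchored
    displacement. Implements the forward-backward dynamic program over
    per-path Needleman-Wunsch matrices, displacement tabulation over path
    pairs, GFA input and GAF output, brute-force reference oracles, a
    synthetic recombinant simulator for bacterial mosaic genes, and
    alignment-accuracy metrics (Jaccard node similarity, edit distance,
    minimum path switches, breakpoint error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
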