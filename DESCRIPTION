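Package: kpaths
Title: Memory-Efficient k-Best Path Decoding for Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact decoding of the k most probable state paths through a
    hidden Markov model. Provides a naive list-Viterbi reference decoder and
    a memory-efficient decoder that maintains a compressed tree of path and
    state nodes with online pruning and run merging, so that only back
    pointers still reachable from the current frontier are kept alive.
    Includes the forward algorithm, utilities for mapping state paths to
    labellings and transmembrane-protein topologies (helix count plus
    sidedness), two topology correctness measures, grouping of paths by
    predicted topology, three consensus-labelling strategies, confidence
    reporting based on conditional path probability mass, and seeded
    generators for random models and membrane-protein-like fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
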