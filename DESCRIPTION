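Package: archflux
Title: Replichore Architecture and Gene Flux Analysis for Reduced Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for small circular bacterial genomes
    such as the honeybee symbiont Lactobacillus kunkeei: GC-skew profiling with
    origin/terminus (ori/ter) localization and dif-site scanning, circular
    distance-to-origin arithmetic with rank-based tests for positional bias of
    gene functional categories, ancestral gene-content reconstruction on a
    rooted species tree by generalized (Sankoff) parsimony under an
    event-cost scheme with per-branch gain/loss flux summaries, bootstrapped
    gene-tree congruence tallies (supported sister pairs, group monophyly,
    Robinson-Foulds host congruence), a pairwise-homoplasy (Phi) permutation
    screen for recombination, and growth-curve/replication-ratio
    calculations. A synthetic-data module generates every input with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
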