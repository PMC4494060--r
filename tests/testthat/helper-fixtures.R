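## Shared fixtures and independent oracles for the test suite. Everything is
## built in code at test time; no binary fixtures.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## A tiny circular genome with a known sequence.
tiny_genome <- function(seq = "ACGTACGTAC", ori = 0, ter = 5, id = "tiny") {
  circular_genome(id = id, length = nchar(seq), ori = ori, ter = ter,
                  sequence = seq)
}

## Exhaustive-enumeration oracle for the generalized-parsimony cost: tries
## every assignment of states to internal nodes, charging the root state as
## an acquisition from absence (same convention as the reconstruction).
brute_sankoff_cost <- function(tree, tips, costs) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  S <- costs$max_copies + 1L
  grid <- as.matrix(expand.grid(rep(list(0:(S - 1L)), nnode)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    st <- c(tips[tree$tip.label], grid[r, ])
    cost <- transition_cost(0, st[ntip + 1L], costs)
    for (k in seq_len(nrow(tree$edge)))
      cost <- cost + transition_cost(st[tree$edge[k, 1]],
                                     st[tree$edge[k, 2]], costs)
    if (cost < best) best <- cost
  }
  best
}

## Sum of per-branch transition costs implied by a reconstruction (for the
## event/cost consistency check), including the root origination.
recon_path_cost <- function(rec, fam = 1L) {
  tree <- rec$tree
  ntip <- length(tree$tip.label)
  cost <- transition_cost(0, rec$states[ntip + 1L, fam], rec$costs)
  for (k in seq_len(nrow(tree$edge)))
    cost <- cost + transition_cost(rec$states[tree$edge[k, 1], fam],
                                   rec$states[tree$edge[k, 2], fam],
                                   rec$costs)
  cost
}

## Brute-force oracle for pairwise site incompatibility: minimum joint
## parsimony length over all unrooted topologies, minus the per-site state
## lower bounds.
brute_pair_incompat <- function(col_i, col_j) {
  keep <- !(col_i %in% c("-", "N")) & !(col_j %in% c("-", "N"))
  ci <- col_i[keep]; cj <- col_j[keep]
  n <- length(ci)
  labs <- paste0("s", seq_len(n))
  dat <- phangorn::phyDat(matrix(c(ci, cj), nrow = n,
                                 dimnames = list(labs, NULL)),
                          type = "USER", levels = c("A", "C", "G", "T"))
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  best <- min(vapply(trees, function(tr) phangorn::parsimony(tr, dat),
                     numeric(1)))
  best - (length(unique(ci)) - 1L) - (length(unique(cj)) - 1L)
}

## Quartet trees used for clonal / recombinant alignment simulations: long
## internal branch so the two topologies are strongly supported.
quartet_ab_cd <- function()
  ape::read.tree(text = "((A:0.3,B:0.3):1.5,(C:0.3,D:0.3):1.5);")
quartet_ac_bd <- function()
  ape::read.tree(text = "((A:0.3,C:0.3):1.5,(B:0.3,D:0.3):1.5);")

## Swap two tip labels (alternative gene-tree topologies).
swap_tips <- function(tr, a, b) {
  i <- match(a, tr$tip.label); j <- match(b, tr$tip.label)
  tr$tip.label[c(i, j)] <- c(b, a)
  tr
}

## Single-family ortholog matrix from a named count vector.
fam_matrix <- function(counts, fam = "f1") {
  ortholog_matrix(matrix(counts, nrow = 1,
                         dimnames = list(fam, names(counts))))
}
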