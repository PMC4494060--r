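## Synthetic-data generators with known ground truth for every pipeline
## input: planted-skew circular genomes, category-biased gene positions,
## gene-family evolution on a known tree with a full event log, gene-tree
## sets from topology mixtures with bootstrap-like supports, clonal vs
## recombinant alignments, and growth curves. Every generator is a pure
## function of (parameters, seed); the planted truth is attached as the
## `truth` attribute.

#' Simulate a circular genome with a planted replichore skew
#'
#' Base composition is uniform over A, C, G, T except that the G and C
#' probabilities are tilted by `skew_amp` toward G on the ori-to-ter arc
#' (the forward-strand leading strand) and toward C on the complementary
#' arc, so the expected window GC skew is about +/- `skew_amp` on the two
#' replichores.
#'
#' @param length genome length in bp.
#' @param ori,ter planted origin and terminus positions (0-based).
#' @param skew_amp skew amplitude in \[0, 1\].
#' @param seed integer seed.
#' @return a [circular_genome()] with a `truth` attribute recording the
#'   planted parameters.
#' @export
simulate_genome <- function(length, ori, ter, skew_amp, seed) {
  if (skew_amp < 0 || skew_amp > 1) stop_arch("skew_amp must be in [0,1]")
  length <- as.integer(length)
  ori <- as.integer(pmod(ori, length)); ter <- as.integer(pmod(ter, length))
  if (ori == ter) stop_arch("ori and ter coincide")
  seq <- with_seed(seed, {
    pos <- 0:(length - 1L)
    on_leading <- pmod(pos - ori, length) < pmod(ter - ori, length)
    pG <- ifelse(on_leading, 0.25 * (1 + skew_amp), 0.25 * (1 - skew_amp))
    pC <- 0.5 - pG
    u <- runif(length)
    ifelse(u < pG, "G",
           ifelse(u < 0.5, "C", ifelse(u < 0.75, "A", "T")))
  })
  g <- circular_genome(id = paste0("sim", seed), length = length,
                       ori = ori, ter = ter,
                       sequence = paste(seq, collapse = ""))
  attr(g, "truth") <- list(scenario = "planted_skew", seed = seed,
                           ori = ori, ter = ter, skew_amp = skew_amp)
  g
}

#' Simulate gene positions with category-specific positional bias
#'
#' Distances to ori are drawn per category: `ori_proximal` from a triangular
#' distribution peaked at 0, `ter_proximal` peaked at L/2, `uniform` flat on
#' \[0, L/2\]; each gene is placed at that distance on a random side of ori.
#'
#' @param n_genes total number of genes.
#' @param categories data.frame with columns `category`, `bias`
#'   (ori_proximal / ter_proximal / uniform) and `weight` (relative
#'   frequencies, recycled to sum 1).
#' @param genome a [circular_genome()].
#' @param seed integer seed.
#' @param gene_span gene length in bp.
#' @return a [gene_table()] with a `truth` attribute.
#' @export
simulate_gene_positions <- function(n_genes, categories, genome, seed,
                                    gene_span = 900L) {
  if (n_genes < 1L) stop_arch("n_genes must be >= 1")
  bad <- setdiff(categories$bias, c("ori_proximal", "ter_proximal", "uniform"))
  if (length(bad)) stop_arch("unknown bias spec: ", paste(bad, collapse = ", "))
  L <- genome$length
  half <- L / 2
  with_seed(seed, {
    w <- categories$weight %||% rep(1, nrow(categories))
    ci <- sample.int(nrow(categories), n_genes, replace = TRUE,
                     prob = w / sum(w))
    u <- runif(n_genes)
    d <- numeric(n_genes)
    b <- categories$bias[ci]
    d[b == "ori_proximal"] <- half * (1 - sqrt(u[b == "ori_proximal"]))
    d[b == "ter_proximal"] <- half * sqrt(u[b == "ter_proximal"])
    d[b == "uniform"] <- half * u[b == "uniform"]
    side <- sample(c(-1, 1), n_genes, replace = TRUE)
    mid <- pmod(round(genome$ori + side * d), L)
    start <- pmod(mid - gene_span %/% 2L, L)
    end <- pmod(start + gene_span, L)
    ## avoid degenerate start == end on tiny genomes
    end[end == start] <- pmod(end[end == start] + 1L, L)
    g <- gene_table(gene_id = sprintf("g%04d", seq_len(n_genes)),
                    genome_id = genome$id, start = start, end = end,
                    strand = sample(c("+", "-"), n_genes, replace = TRUE),
                    category = categories$category[ci])
    attr(g, "truth") <- list(scenario = "category_bias", seed = seed,
                             categories = categories,
                             true_distance = d)
    g
  })
}

## Gillespie-style event sampling for one family along one branch.
## State 0 can only be gained; states >= 1 can be lost, duplicated, or (for
## states >= 2) contracted at the duplication rate.
.evolve_branch <- function(state, len, gain_rate, loss_rate, dup_rate,
                           max_copies) {
  t <- 0
  log <- list()
  repeat {
    rates <- if (state == 0L) c(gain = gain_rate)
             else c(loss = loss_rate,
                    dup = if (state < max_copies) dup_rate else 0,
                    contract = if (state >= 2L) dup_rate else 0)
    tot <- sum(rates)
    if (tot <= 0) break
    t <- t + rexp(1, tot)
    if (t > len) break
    ev <- sample(names(rates), 1, prob = rates / tot)
    new_state <- switch(ev, gain = 1L, loss = 0L, dup = state + 1L,
                        contract = state - 1L)
    log[[length(log) + 1L]] <- list(type = switch(ev, gain = "gain",
                                                  loss = "loss",
                                                  dup = "expansion",
                                                  contract = "contraction"),
                                    time = t, from = state, to = new_state)
    state <- new_state
  }
  list(state = state, log = log)
}

#' Simulate gene-family content evolution on a species tree
#'
#' Families evolve independently along the branches of a rooted tree with
#' branch lengths: absent families are gained at `gain_rate` (per unit branch
#' length), present families are lost at `loss_rate` or change copy number at
#' `dup_rate`. A focal branch may have its loss rate multiplied to plant a
#' genome-reduction signature. Every sampled event is recorded.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param root_families number of families present (single copy) at the root.
#' @param gain_rate,loss_rate,dup_rate event rates per unit branch length.
#' @param focal_branch optional child-node name of the branch whose loss rate
#'   is multiplied by `focal_multiplier`.
#' @param focal_multiplier loss-rate multiplier on the focal branch.
#' @param seed integer seed.
#' @param novel_families families absent at the root that may be gained along
#'   the tree.
#' @param max_copies copy-number cap.
#' @return an [ortholog_matrix()] of leaf copy numbers with a `truth`
#'   attribute holding the per-branch true event log and per-branch
#'   loss/gain counts. Families entirely absent from all leaves are dropped
#'   from the matrix (but kept in the log).
#' @export
simulate_gene_content_evolution <- function(tree, root_families,
                                            gain_rate, loss_rate, dup_rate,
                                            focal_branch = NULL,
                                            focal_multiplier = 1,
                                            seed = 1L,
                                            novel_families = 0L,
                                            max_copies = 8L) {
  if (is.null(tree$edge.length)) stop_arch("tree needs branch lengths")
  if (!ape::is.rooted(tree)) stop_arch("tree must be rooted")
  if (any(c(gain_rate, loss_rate, dup_rate) < 0)) stop_arch("rates must be >= 0")
  n_fam <- root_families + novel_families
  if (n_fam == 0L) stop_arch("no families to simulate")
  ntip <- length(tree$tip.label)
  lab_ok <- !is.null(tree$node.label) && all(nzchar(tree$node.label)) &&
    !anyDuplicated(tree$node.label) &&
    all(is.na(suppressWarnings(as.numeric(tree$node.label))))
  node_names <- c(tree$tip.label,
                  if (lab_ok) tree$node.label
                  else paste0("node", seq_len(tree$Nnode) + ntip))
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  elen <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  branch_names <- node_names[edge[, 2]]
  if (!is.null(focal_branch) && !focal_branch %in% branch_names)
    stop_arch("focal branch '", focal_branch, "' not found")
  fams <- sprintf("fam%05d", seq_len(n_fam))
  with_seed(seed, {
    states <- matrix(0L, nrow = ntip + tree$Nnode, ncol = n_fam)
    states[ntip + 1L, seq_len(root_families)] <- 1L
    logs <- list()
    for (k in seq_len(nrow(edge))) {
      par <- edge[k, 1]; ch <- edge[k, 2]
      lr <- loss_rate *
        (if (!is.null(focal_branch) && branch_names[k] == focal_branch)
           focal_multiplier else 1)
      for (f in seq_len(n_fam)) {
        res <- .evolve_branch(states[par, f], elen[k], gain_rate, lr,
                              dup_rate, max_copies)
        states[ch, f] <- res$state
        if (length(res$log)) {
          for (ev in res$log)
            logs[[length(logs) + 1L]] <- data.frame(
              family = fams[f], branch = branch_names[k], type = ev$type,
              time = ev$time, from = ev$from, to = ev$to,
              stringsAsFactors = FALSE)
        }
      }
    }
    event_log <- if (length(logs)) do.call(rbind, logs)
                 else data.frame(family = character(0), branch = character(0),
                                 type = character(0), time = numeric(0),
                                 from = integer(0), to = integer(0))
    leaf <- t(states[seq_len(ntip), , drop = FALSE])
    dimnames(leaf) <- list(fams, tree$tip.label)
    keep <- rowSums(leaf) > 0
    mat <- ortholog_matrix(leaf[keep, , drop = FALSE])
    true_losses <- tapply(event_log$type == "loss", event_log$branch, sum)
    true_gains <- tapply(event_log$type == "gain", event_log$branch, sum)
    attr(mat, "truth") <- list(
      scenario = "gene_content", seed = seed,
      states = `dimnames<-`(states, list(node_names, fams)),
      event_log = event_log,
      true_losses = true_losses, true_gains = true_gains,
      focal_branch = focal_branch, focal_multiplier = focal_multiplier,
      dropped_families = fams[!keep])
    mat
  })
}

#' Simulate a bootstrapped gene-tree set from a topology mixture
#'
#' Each gene tree's topology is drawn from the supplied mixture (the species
#' tree plus alternative topologies); every internal node receives a
#' bootstrap-like support drawn from a normal distribution truncated to
#' \[0, 100\].
#'
#' @param species_tree `phylo`; the mixture's first component.
#' @param n_trees number of gene trees.
#' @param alt_topologies list of `list(tree =, weight =)` alternatives; the
#'   species tree receives the remaining weight (all weights must sum to 1
#'   and be non-negative).
#' @param support_mean,support_sd support distribution parameters (percent).
#' @param seed integer seed.
#' @return a `multiPhylo` with per-tree `support` vectors and a `truth`
#'   attribute recording the mixture and the drawn component of every tree.
#' @export
simulate_gene_trees <- function(species_tree, n_trees, alt_topologies = list(),
                                support_mean = 99, support_sd = 2, seed = 1L) {
  alt_w <- vapply(alt_topologies, `[[`, numeric(1), "weight")
  w0 <- 1 - sum(alt_w)
  if (w0 < -1e-9 || any(alt_w < 0)) stop_arch("mixture weights must sum to 1")
  comps <- c(list(species_tree), lapply(alt_topologies, `[[`, "tree"))
  weights <- c(max(w0, 0), alt_w)
  with_seed(seed, {
    pick <- sample.int(length(comps), n_trees, replace = TRUE, prob = weights)
    trees <- lapply(seq_len(n_trees), function(i) {
      tr <- comps[[pick[i]]]
      sup <- rnorm(tr$Nnode, support_mean, support_sd)
      tr$support <- pmin(100, pmax(0, sup))
      tr$node.label <- format(round(tr$support, 1), trim = TRUE)
      tr
    })
    class(trees) <- "multiPhylo"
    attr(trees, "truth") <- list(scenario = "topology_mixture", seed = seed,
                                 weights = weights, component = pick)
    trees
  })
}

## Evolve one site set down a tree under the equal-rates (Jukes-Cantor)
## model; returns tips x sites character matrix.
.evolve_sites <- function(tree, n_sites, subst_rate) {
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  elen <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  seqs <- matrix(NA_integer_, nrow = ntip + tree$Nnode, ncol = n_sites)
  seqs[ntip + 1L, ] <- sample.int(4L, n_sites, replace = TRUE)
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    p_change <- 0.75 * (1 - exp(-4 / 3 * subst_rate * elen[k]))
    x <- seqs[par, ]
    hit <- runif(n_sites) < p_change
    if (any(hit)) {
      ## draw a different base uniformly
      x[hit] <- ((x[hit] - 1L + sample.int(3L, sum(hit), replace = TRUE)) %% 4L) + 1L
    }
    seqs[ch, ] <- x
  }
  m <- matrix(bases[seqs[seq_len(ntip), ]], nrow = ntip)
  rownames(m) <- tree$tip.label
  m
}

#' Simulate a (possibly recombinant) alignment from tree segments
#'
#' Each segment evolves independently on its own tree under an equal-rates
#' substitution model from a random root sequence; segments are concatenated.
#' One segment yields clonal data; two or more segments with different
#' topologies plant recombination breakpoints.
#'
#' @param tree_segments list of `list(tree =, n_sites =)`; all trees must
#'   share the same leaf set and carry branch lengths.
#' @param subst_rate substitution rate per site per unit branch length.
#' @param seed integer seed.
#' @return character matrix alignment with a `truth` attribute holding the
#'   breakpoint positions (last column of each non-final segment).
#' @export
simulate_alignment <- function(tree_segments, subst_rate, seed = 1L) {
  if (!length(tree_segments)) stop_arch("need at least one segment")
  if (subst_rate <= 0) stop_arch("substitution rate must be positive")
  ns <- vapply(tree_segments, `[[`, numeric(1), "n_sites")
  if (any(ns <= 0)) stop_arch("zero-length segment")
  with_seed(seed, {
    tips <- sort(tree_segments[[1]]$tree$tip.label)
    mats <- lapply(tree_segments, function(seg) {
      if (!setequal(seg$tree$tip.label, tips))
        stop_arch("segment trees must share the same leaf set")
      .evolve_sites(seg$tree, seg$n_sites, subst_rate)[tips, , drop = FALSE]
    })
    aln <- do.call(cbind, mats)
    attr(aln, "truth") <- list(scenario = "segmented_alignment", seed = seed,
                               breakpoints = if (length(ns) > 1)
                                 cumsum(ns)[-length(ns)] else integer(0))
    aln
  })
}

#' Simulate a growth curve
#'
#' od(t) = od0 * 2^(t / doubling) * exp(eps), eps ~ Normal(0, noise_sd),
#' optionally preceded by a lag phase and capped at a stationary plateau.
#'
#' @param doubling true doubling time (min).
#' @param t_max total duration (min).
#' @param interval sampling interval (min).
#' @param noise_sd multiplicative (log-scale) noise standard deviation.
#' @param seed integer seed.
#' @param od0 initial OD.
#' @param lag lag-phase duration (min; OD stays at od0).
#' @param plateau maximum OD (stationary phase).
#' @return data.frame with `time_min` and `od`, plus a `truth` attribute.
#' @export
simulate_growth_curve <- function(doubling, t_max, interval, noise_sd = 0,
                                  seed = 1L, od0 = 0.05, lag = 0,
                                  plateau = Inf) {
  if (doubling <= 0 || t_max <= 0 || interval <= 0)
    stop_arch("doubling, t_max and interval must be positive")
  with_seed(seed, {
    t <- seq(0, t_max, by = interval)
    grow_t <- pmax(t - lag, 0)
    od <- pmin(od0 * 2^(grow_t / doubling), plateau)
    if (noise_sd > 0) od <- od * exp(rnorm(length(t), 0, noise_sd))
    out <- data.frame(time_min = t, od = od)
    attr(out, "truth") <- list(scenario = "growth_curve", seed = seed,
                               doubling = doubling, noise_sd = noise_sd,
                               lag = lag, plateau = plateau)
    out
  })
}
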