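## Gene-tree congruence: supported sister-pair tallies across bootstrapped
## gene trees, group monophyly reports, and Robinson-Foulds congruence
## between a bacterial tree and a host tree.

## Per-internal-node supports on the percent scale (NA = missing).
.supports <- function(tree) {
  if (!is.null(tree$support)) return(tree$support)
  .normalize_supports(tree)$support
}

#' Supported sister pairs (cherries) of one tree
#'
#' Returns every unordered leaf pair that forms a cherry (two leaves
#' subtended by a single internal node) whose node support strictly exceeds
#' the threshold. Missing supports fail the threshold. With
#' `mode = "bipartition"` a pair also qualifies when any supported internal
#' edge separates exactly that pair from all remaining leaves.
#'
#' @param tree a `phylo` with supports (see [read_trees()]).
#' @param threshold support threshold in percent; comparison is strict (>).
#' @param mode `"cherry"` (default) or `"bipartition"`.
#' @return character matrix with two columns, one row per pair (possibly
#'   zero rows), each row sorted alphabetically.
#' @export
supported_sister_pairs <- function(tree, threshold = 95,
                                   mode = c("cherry", "bipartition")) {
  mode <- match.arg(mode)
  ntip <- length(tree$tip.label)
  sup <- .supports(tree)
  out <- matrix(character(0), ncol = 2)
  if (mode == "cherry") {
    kids <- split(tree$edge[, 2], tree$edge[, 1])
    for (v in as.integer(names(kids))) {
      ch <- kids[[as.character(v)]]
      if (length(ch) == 2L && all(ch <= ntip)) {
        s <- sup[v - ntip]
        if (!is.na(s) && s > threshold)
          out <- rbind(out, sort(tree$tip.label[ch]))
      }
    }
  } else {
    parts <- ape::prop.part(tree)
    for (v in seq_along(parts)) {
      tips <- parts[[v]]
      side <- if (length(tips) == 2L) tips
              else if (ntip - length(tips) == 2L) setdiff(seq_len(ntip), tips)
              else NULL
      if (!is.null(side)) {
        s <- sup[v]
        if (!is.na(s) && s > threshold)
          out <- rbind(out, sort(tree$tip.label[side]))
      }
    }
    out <- unique(out)
  }
  colnames(out) <- c("taxon_a", "taxon_b")
  out
}

#' Tally supported sister pairs across a gene-tree set
#'
#' Counts, for every pair of taxa, the number of trees in which the pair is a
#' supported cherry. Pairs observed in fewer than `rare_fraction` of the
#' trees (but at least once) are listed as rare arrangements. Trees missing a
#' taxon simply cannot contribute to its pairs; the denominator stays the
#' total number of trees.
#'
#' @param treeset a `multiPhylo` gene-tree set.
#' @param threshold support threshold in percent (strict).
#' @param rare_fraction fraction below which an observed pair is "rare".
#' @param taxa optional taxon namespace (default: union of tip labels).
#' @inheritParams supported_sister_pairs
#' @return object of class `sister_tally`: symmetric `counts` matrix,
#'   `n_trees`, and `rare_pairs` data.frame.
#' @export
tally_sister_support <- function(treeset, threshold = 95,
                                 rare_fraction = 0.01, taxa = NULL,
                                 mode = c("cherry", "bipartition")) {
  mode <- match.arg(mode)
  if (!length(treeset)) stop_arch("empty tree set")
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(treeset, `[[`, "tip.label"))))
  counts <- matrix(0L, length(taxa), length(taxa),
                   dimnames = list(taxa, taxa))
  for (tr in treeset) {
    prs <- supported_sister_pairs(tr, threshold, mode)
    for (i in seq_len(nrow(prs))) {
      a <- prs[i, 1]; b <- prs[i, 2]
      counts[a, b] <- counts[a, b] + 1L
      counts[b, a] <- counts[b, a] + 1L
    }
  }
  n_trees <- length(treeset)
  ut <- which(upper.tri(counts), arr.ind = TRUE)
  cnt <- counts[ut]
  rare <- cnt > 0L & cnt < rare_fraction * n_trees
  rare_pairs <- data.frame(taxon_a = taxa[ut[rare, 1]],
                           taxon_b = taxa[ut[rare, 2]],
                           count = cnt[rare], stringsAsFactors = FALSE)
  structure(list(taxa = taxa, counts = counts, n_trees = n_trees,
                 threshold = threshold, rare_fraction = rare_fraction,
                 rare_pairs = rare_pairs),
            class = "sister_tally")
}

#' @export
print.sister_tally <- function(x, ...) {
  cat("Sister-pair tally over ", x$n_trees, " trees (support > ",
      x$threshold, "%)\n", sep = "")
  ut <- which(upper.tri(x$counts) & x$counts > 0, arr.ind = TRUE)
  if (nrow(ut)) {
    ord <- order(-x$counts[ut])
    for (i in head(ord, 10))
      cat(sprintf("  %s -- %s: %d\n", x$taxa[ut[i, 1]], x$taxa[ut[i, 2]],
                  x$counts[ut][i]))
    if (nrow(ut) > 10) cat("  ...\n")
  } else cat("  no supported pairs\n")
  if (nrow(x$rare_pairs))
    cat("  rare arrangements (<", 100 * x$rare_fraction, "% of trees): ",
        nrow(x$rare_pairs), "\n", sep = "")
  invisible(x)
}

#' Monophyly support of named groups across a gene-tree set
#'
#' A tree supports the group configuration iff every group with at least two
#' members present in the tree forms a clade whose subtending node support
#' strictly exceeds the threshold. Singleton (or absent) groups are
#' vacuously monophyletic.
#'
#' @param treeset a `multiPhylo`.
#' @param groups named list of disjoint character vectors of taxa.
#' @param threshold support threshold in percent (strict).
#' @return object of class `monophyly_report` with `per_tree` (logical),
#'   `n_support` and `n_trees`.
#' @export
monophyly_support <- function(treeset, groups, threshold = 95) {
  all_members <- unlist(groups)
  if (anyDuplicated(all_members)) stop_arch("groups overlap")
  verdict <- vapply(treeset, function(tr) {
    ntip <- length(tr$tip.label)
    sup <- .supports(tr)
    for (g in groups) {
      present <- intersect(g, tr$tip.label)
      if (length(present) < 2L) next
      mrca <- ape::getMRCA(tr, present)
      desc <- ape::extract.clade(tr, mrca)$tip.label
      if (!setequal(desc, present)) return(FALSE)
      s <- sup[mrca - ntip]
      if (is.na(s) || s <= threshold) return(FALSE)
    }
    TRUE
  }, logical(1))
  structure(list(groups = groups, threshold = threshold,
                 per_tree = verdict, n_support = sum(verdict),
                 n_trees = length(verdict)),
            class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat(x$n_support, " of ", x$n_trees,
      " trees support monophyly of all groups (support > ", x$threshold,
      "%)\n", sep = "")
  invisible(x)
}

#' Topological congruence between a bacterial and a host tree
#'
#' Relabels the host tree through the bacterium-to-host mapping, restricts
#' both trees to the shared leaves, and computes the unrooted Robinson-Foulds
#' distance, the number of shared non-trivial bipartitions, and the RF
#' distance normalized by its maximum 2(n - 3).
#'
#' @param bact_tree,host_tree `phylo` objects.
#' @param mapping data.frame with columns `bact` and `host` (an injective
#'   leaf mapping), or a named character vector `host_leaf = f(bact_leaf)`
#'   with bacterial leaves as names.
#' @return object of class `congruence_result`.
#' @export
host_congruence <- function(bact_tree, host_tree, mapping) {
  if (is.data.frame(mapping)) {
    map <- setNames(as.character(mapping$host), as.character(mapping$bact))
  } else map <- mapping
  if (anyDuplicated(map[!is.na(map)]) || anyDuplicated(names(map)))
    stop_arch("mapping must be injective")
  map <- map[names(map) %in% bact_tree$tip.label &
             map %in% host_tree$tip.label]
  if (length(map) < 4L) stop_arch("fewer than 4 mapped shared leaves")
  ## relabel host leaves with the bacterial names
  inv <- setNames(names(map), map)
  host <- host_tree
  keep_host <- host$tip.label %in% names(inv)
  host <- ape::keep.tip(host, host$tip.label[keep_host])
  host$tip.label <- unname(inv[host$tip.label])
  bact <- ape::keep.tip(bact_tree, names(map))
  ub <- ape::unroot(bact); uh <- ape::unroot(host)
  ub$node.label <- NULL; uh$node.label <- NULL
  rf <- phangorn::RF.dist(ub, uh, normalize = FALSE, check.labels = TRUE)
  n <- length(map)
  nb_b <- ub$Nnode - 1L   # non-trivial splits in each unrooted tree
  nb_h <- uh$Nnode - 1L
  shared <- (nb_b + nb_h - rf) / 2
  structure(list(n_shared_leaves = n, shared_bipartitions = shared,
                 rf_distance = rf,
                 normalized_rf = if (n > 3) rf / (2 * (n - 3)) else NA_real_,
                 mapping = map),
            class = "congruence_result")
}

#' @export
print.congruence_result <- function(x, ...) {
  cat(sprintf(
    "Host congruence on %d shared leaves: RF = %d (normalized %.3f), %g shared bipartitions\n",
    x$n_shared_leaves, x$rf_distance, x$normalized_rf,
    x$shared_bipartitions))
  invisible(x)
}
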