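## Positional functional bias: do gene functional categories sit at different
## distances from the replication origin? Global Kruskal-Wallis test plus
## pairwise Mann-Whitney post hocs with Bonferroni correction.

#' Build a category/distance table
#'
#' One row per categorized gene with its circular distance to the replication
#' origin of its genome. Genes without a category are counted and reported in
#' the `n_uncategorized` attribute but excluded from the table.
#'
#' @param genes a [gene_table()].
#' @param genomes list of [circular_genome()] objects covering every
#'   `genome_id` in `genes`.
#' @return data.frame of class `distance_table` with columns `gene_id`,
#'   `genome_id`, `category`, `distance_bp`; attribute `n_uncategorized`.
#' @export
build_distance_table <- function(genes, genomes) {
  if (inherits(genomes, "circular_genome")) genomes <- list(genomes)
  names(genomes) <- vapply(genomes, `[[`, "", "id")
  unknown <- setdiff(unique(genes$genome_id), names(genomes))
  if (length(unknown))
    stop_arch("genes reference unknown genome(s): ",
              paste(unknown, collapse = ", "))
  dist <- integer(nrow(genes))
  for (g in names(genomes)) {
    sel <- genes$genome_id == g
    if (any(sel))
      dist[sel] <- distance_to_ori(genes[sel, , drop = FALSE], genomes[[g]])
  }
  keep <- nzchar(genes$category)
  out <- data.frame(gene_id = genes$gene_id[keep],
                    genome_id = genes$genome_id[keep],
                    category = genes$category[keep],
                    distance_bp = dist[keep], stringsAsFactors = FALSE)
  attr(out, "n_uncategorized") <- sum(!keep)
  class(out) <- c("distance_table", "data.frame")
  out
}

## Categories with at least min_group members; errors if fewer than 2 remain.
.eligible_split <- function(table, min_group) {
  groups <- split(table$distance_bp, table$category)
  small <- names(groups)[lengths(groups) < min_group]
  groups <- groups[lengths(groups) >= min_group]
  if (length(groups) < 2L)
    stop_arch("fewer than 2 categories with >= ", min_group, " genes")
  list(groups = groups, excluded = small)
}

#' Global Kruskal-Wallis test of positional bias
#'
#' Tests whether the distances to ori differ among functional categories.
#' The H statistic uses mean ranks for ties and the standard tie correction;
#' the p-value comes from the chi-square approximation with k - 1 degrees of
#' freedom. Categories with fewer than `min_group` genes are excluded and
#' listed in the result.
#'
#' @param table a [build_distance_table()] result (pooled across genomes or a
#'   per-genome subset; to pool genomes of different size, normalize
#'   `distance_bp` by L/2 first).
#' @param min_group minimum category size to enter the test.
#' @return list of class `bias_test` with `H`, `df`, `p_global`,
#'   `n_per_category` and `excluded_categories`.
#' @export
kruskal_wallis_bias <- function(table, min_group = 5L) {
  es <- .eligible_split(table, min_group)
  x <- unlist(es$groups, use.names = FALSE)
  g <- factor(rep(names(es$groups), lengths(es$groups)))
  kt <- stats::kruskal.test(x, g)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_global = kt$p.value,
                 n_per_category = lengths(es$groups),
                 excluded_categories = es$excluded),
            class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis positional-bias test: H = %.4f, df = %d, p = %.3g\n",
              x$H, x$df, x$p_global))
  cat("  categories:", paste(names(x$n_per_category), "(n=",
                             x$n_per_category, ")", sep = "",
                             collapse = ", "), "\n")
  if (length(x$excluded_categories))
    cat("  excluded (too small):",
        paste(x$excluded_categories, collapse = ", "), "\n")
  invisible(x)
}

## Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
## assignments of the pooled (possibly tied) values to group 1. Two-sided
## p = 2 * min(P(W <= w), P(W >= w)), capped at 1. Feasible for n <= 8/group.
.mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  combs <- combn(length(pooled), n1)
  ws <- colSums(matrix(r[combs], nrow = n1))
  ncomb <- length(ws)
  eps <- 1e-9
  p_le <- sum(ws <= w_obs + eps) / ncomb
  p_ge <- sum(ws >= w_obs - eps) / ncomb
  min(1, 2 * min(p_le, p_ge))
}

## Normal-approximation two-sided Mann-Whitney p with tie and continuity
## correction (delegates to stats::wilcox.test).
.mw_approx_p <- function(x, y) {
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                      correct = TRUE))$p.value
}

#' Pairwise Mann-Whitney tests with Bonferroni correction
#'
#' Every pair of eligible categories is compared two-sided. When both groups
#' have at most `exact_max` members, the exact permutation distribution of
#' the rank sum is fully enumerated (valid under ties); larger comparisons
#' use the normal approximation with tie and continuity correction. The
#' Bonferroni factor is the number of pairs actually tested.
#'
#' @inheritParams kruskal_wallis_bias
#' @param exact_max largest per-group size for the exact test.
#' @return data.frame of class `pairwise_bias` with one row per pair:
#'   `cat_i`, `cat_j`, `U`, `p_raw`, `p_adjusted`.
#' @export
pairwise_mannwhitney <- function(table, min_group = 5L, exact_max = 8L) {
  es <- .eligible_split(table, min_group)
  cats <- names(es$groups)
  pairs <- combn(cats, 2)
  n_pairs <- ncol(pairs)
  res <- data.frame(cat_i = pairs[1, ], cat_j = pairs[2, ],
                    U = NA_real_, p_raw = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(n_pairs)) {
    x <- es$groups[[pairs[1, k]]]
    y <- es$groups[[pairs[2, k]]]
    r <- rank(c(x, y))
    res$U[k] <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    res$p_raw[k] <- if (length(x) <= exact_max && length(y) <= exact_max)
      .mw_exact_p(x, y) else .mw_approx_p(x, y)
  }
  res$p_adjusted <- pmin(1, res$p_raw * n_pairs)
  attr(res, "n_pairs") <- n_pairs
  attr(res, "excluded_categories") <- es$excluded
  class(res) <- c("pairwise_bias", "data.frame")
  res
}

#' Count flagged genes near the replication origin
#'
#' @param genes a [gene_table()] for one genome.
#' @param genome the [circular_genome()].
#' @param class_flag flag to select genes (e.g. `"secreted"`).
#' @param window_bp distance cutoff on either side of ori (at most L/2).
#' @return named integer vector `c(n_in, n_total)`: flagged genes within
#'   `window_bp` of ori, and all flagged genes. Unknown flags give
#'   `c(0, 0)` with a warning.
#' @export
count_gene_class_near_ori <- function(genes, genome, class_flag, window_bp) {
  if (window_bp > genome$length / 2)
    stop_arch("window_bp exceeds half the genome length")
  sel <- has_flag(genes, class_flag)
  if (!any(sel)) {
    warning("no genes carry flag '", class_flag, "'", call. = FALSE)
    return(c(n_in = 0L, n_total = 0L))
  }
  d <- distance_to_ori(genes[sel, , drop = FALSE], genome)
  c(n_in = sum(d <= window_bp), n_total = sum(sel))
}
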