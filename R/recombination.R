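## Alignment-level recombination screen: pairwise homoplasy (Phi) statistic
## with a site-permutation null, pairwise identity arithmetic, and the
## all-tests positivity filter with summary fractions.

MISSING_CHARS <- c("-", "N", "?", ".")

#' Pairwise sequence identity within an alignment
#'
#' @param aln character matrix alignment (see [read_alignment()]).
#' @param seq_a,seq_b row ids of the two sequences.
#' @param gap_mode `"exclude_gap_columns"` drops columns where either
#'   sequence has a gap or N from the denominator; `"count_gaps"` keeps all
#'   columns and scores gap-vs-base as a mismatch (gap-vs-gap matches).
#' @return object of class `identity_result` with `aligned_length` (the
#'   effective denominator), `n_mismatches` and `identity_percent` (one
#'   decimal, rounding half away from zero).
#' @export
pairwise_identity <- function(aln, seq_a, seq_b,
                              gap_mode = c("exclude_gap_columns",
                                           "count_gaps")) {
  gap_mode <- match.arg(gap_mode)
  for (id in c(seq_a, seq_b))
    if (!id %in% rownames(aln)) stop_arch("unknown sequence id '", id, "'")
  a <- aln[seq_a, ]; b <- aln[seq_b, ]
  if (gap_mode == "exclude_gap_columns") {
    keep <- !(a %in% MISSING_CHARS | b %in% MISSING_CHARS)
    a <- a[keep]; b <- b[keep]
  }
  len <- length(a)
  if (len == 0L) stop_arch("no comparable columns")
  mm <- sum(a != b)
  structure(list(aligned_length = len, n_mismatches = mm,
                 identity_percent = round_half_up(100 * (1 - mm / len), 1L),
                 identity_exact = 100 * (1 - mm / len)),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("%.1f%% identity (%d mismatches over %d columns)\n",
              x$identity_percent, x$n_mismatches, x$aligned_length))
  invisible(x)
}

## Integer state encoding of alignment columns: 0 = missing, 1.. = states.
.encode_states <- function(aln) {
  codes <- matrix(match(aln, c("A", "C", "G", "T")), nrow = nrow(aln))
  extra <- is.na(codes) & !(aln %in% MISSING_CHARS)
  if (any(extra)) {
    other <- sort(unique(aln[extra]))
    codes[extra] <- 4L + match(aln[extra], other)
  }
  codes[is.na(codes)] <- 0L
  codes
}

#' Parsimony-informative site columns
#'
#' A column is informative when, among sequences with non-missing characters
#' (gaps, N, ? are missing), at least two states are each carried by at least
#' two sequences. Columns with fewer than `min_present` non-missing
#' sequences are excluded.
#'
#' @param aln character matrix alignment.
#' @param min_present minimum non-missing sequences per column.
#' @return integer vector of column indices.
#' @export
informative_sites <- function(aln, min_present = 4L) {
  codes <- .encode_states(aln)
  which(apply(codes, 2, function(col) {
    col <- col[col > 0L]
    if (length(col) < min_present) return(FALSE)
    sum(tabulate(col) >= 2L) >= 2L
  }))
}

#' Refined incompatibility of a pair of informative sites
#'
#' The minimum number of homoplastic (extra) changes any tree must spend to
#' explain both sites jointly, beyond the (s - 1) changes each site needs on
#' its own: the cycle rank of the partition intersection graph whose vertices
#' are the states at the two sites and whose edges are the observed joint
#' patterns. For two binary sites this is the four-gamete test (1 if all four
#' gametes occur, else 0).
#'
#' @param aln character matrix alignment.
#' @param site_i,site_j column indices; both must be informative.
#' @return non-negative integer.
#' @export
site_pair_incompatibility <- function(aln, site_i, site_j) {
  inf <- informative_sites(aln)
  if (!(site_i %in% inf) || !(site_j %in% inf))
    stop_arch("both sites must be parsimony-informative")
  codes <- .encode_states(aln[, c(site_i, site_j), drop = FALSE])
  incompat_matrix(codes)[1, 2]
}

#' Phi (pairwise homoplasy) permutation test for recombination
#'
#' The observed statistic is the mean refined incompatibility over all pairs
#' of parsimony-informative sites at most `window_w` apart in informative-site
#' rank. Recombination makes nearby sites more compatible than distant ones,
#' so the permutation null (shuffling informative-site positions) is tested
#' one-sided: p = (1 + number of permutations with statistic <= observed) /
#' (n_permutations + 1).
#'
#' @param aln character matrix alignment.
#' @param window_w window width in informative-site rank.
#' @param n_permutations number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return object of class `phi_result` with `phi_observed`, `p_value`,
#'   `n_informative_sites`, `window_w`, `n_permutations`, `seed` and
#'   `status` (`"tested"` or `"untestable"`; untestable alignments carry no
#'   p-value).
#' @export
phi_test <- function(aln, window_w = 100L, n_permutations = 1000L,
                     seed = 1L) {
  if (n_permutations < 99L) stop_arch("need at least 99 permutations")
  inf <- informative_sites(aln)
  m <- length(inf)
  if (m < 2L)
    return(structure(list(status = "untestable", n_informative_sites = m,
                          phi_observed = NA_real_, p_value = NA_real_,
                          window_w = window_w,
                          n_permutations = n_permutations, seed = seed),
                     class = "phi_result"))
  M <- incompat_matrix(.encode_states(aln[, inf, drop = FALSE]))
  idx <- which(outer(seq_len(m), seq_len(m),
                     function(i, j) j > i & (j - i) <= window_w),
               arr.ind = TRUE)
  ii <- idx[, 1]; jj <- idx[, 2]
  phi_obs <- mean(M[cbind(ii, jj)])
  eps <- 1e-12
  phi_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
    s <- sample.int(m)
    mean(M[cbind(s[ii], s[jj])])
  }, numeric(1)))
  p <- (1 + sum(phi_perm <= phi_obs + eps)) / (n_permutations + 1)
  structure(list(status = "tested", phi_observed = phi_obs, p_value = p,
                 n_informative_sites = m, window_w = window_w,
                 n_permutations = n_permutations, seed = seed),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  if (x$status == "untestable") {
    cat("Phi test: untestable (", x$n_informative_sites,
        " informative sites)\n", sep = "")
  } else {
    cat(sprintf(
      "Phi test: observed %.4f over %d informative sites (window %d), p = %.4g (%d permutations)\n",
      x$phi_observed, x$n_informative_sites, x$window_w, x$p_value,
      x$n_permutations))
  }
  invisible(x)
}

#' Recombination screen over many genes
#'
#' A gene is called positive only when every provided test (the Phi p-value
#' plus any external per-gene p-values, e.g. from other alignment-based
#' screens) falls strictly below `alpha`. Untestable genes are excluded from
#' the denominator.
#'
#' @param results named list of [phi_test()] results (names are gene ids), or
#'   a data.frame with columns `gene_id`, `p_value` and optionally `status`.
#' @param external optional data.frame with column `gene_id` plus one column
#'   per additional test's p-values; genes with any missing external p are
#'   judged on the available tests.
#' @param alpha positivity threshold (strict <), in (0, 1).
#' @return object of class `screen_summary` with `n_tested`, `n_positive`,
#'   `fraction_percent` (one decimal, rounded half away from zero), `alpha`
#'   and a per-gene `verdicts` data.frame.
#' @export
recombination_screen <- function(results, external = NULL, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop_arch("alpha must be in (0,1)")
  if (is.data.frame(results)) {
    gene_id <- as.character(results$gene_id)
    p <- results$p_value
    status <- if ("status" %in% names(results)) results$status
              else ifelse(is.na(p), "untestable", "tested")
  } else {
    gene_id <- names(results)
    if (is.null(gene_id)) stop_arch("results list must be named by gene id")
    p <- vapply(results, function(r) r$p_value %||% NA_real_, numeric(1))
    status <- vapply(results, `[[`, "", "status")
  }
  if (anyDuplicated(gene_id))
    stop_arch("duplicate gene ids: ",
              paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  testable <- status == "tested" & !is.na(p)
  if (!any(testable)) stop_arch("zero testable genes")
  positive <- testable & p < alpha
  if (!is.null(external)) {
    ext <- external[match(gene_id, external$gene_id), , drop = FALSE]
    pcols <- setdiff(names(ext), "gene_id")
    for (cn in pcols) {
      ep <- ext[[cn]]
      positive <- positive & (is.na(ep) | ep < alpha)
    }
  }
  n_tested <- sum(testable)
  n_positive <- sum(positive)
  verdicts <- data.frame(gene_id = gene_id, p_phi = p, status = status,
                         positive = positive, stringsAsFactors = FALSE)
  structure(list(n_tested = n_tested, n_positive = n_positive,
                 fraction_percent = round_half_up(100 * n_positive / n_tested,
                                                  1L),
                 alpha = alpha, verdicts = verdicts),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf(
    "Recombination screen: %d of %d testable genes positive (%.1f%%) at all-tests p < %g\n",
    x$n_positive, x$n_tested, x$fraction_percent, x$alpha))
  invisible(x)
}
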