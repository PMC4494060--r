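mk_aln <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- paste0("s", seq_along(rows))
  m
}

test_that("pairwise identity handles mismatches and gap modes", {
  aln <- mk_aln("ACGTAC", "ACGTAC")
  expect_equal(pairwise_identity(aln, "s1", "s2")$identity_percent, 100)
  aln2 <- mk_aln("AC", "AG")
  expect_equal(pairwise_identity(aln2, "s1", "s2")$identity_percent, 50)
  # gap columns excluded by default, counted on demand
  aln3 <- mk_aln("AC-T", "ACGT")
  ex <- pairwise_identity(aln3, "s1", "s2")
  expect_equal(ex$aligned_length, 3L)
  expect_equal(ex$n_mismatches, 0L)
  cg <- pairwise_identity(aln3, "s1", "s2", gap_mode = "count_gaps")
  expect_equal(cg$aligned_length, 4L)
  expect_equal(cg$n_mismatches, 1L)
  expect_error(pairwise_identity(aln3, "s1", "zz"), "unknown")
})

test_that("the published 16S comparison arithmetic reproduces", {
  base <- strrep("A", 1408)
  other <- paste0(strrep("G", 17), strrep("A", 1391))
  aln <- mk_aln(base, other)
  r <- pairwise_identity(aln, "s1", "s2")
  expect_equal(r$n_mismatches, 17L)
  expect_equal(r$identity_percent, 98.8)
})

test_that("parsimony-informative sites need two states in two sequences each", {
  aln <- mk_aln("AAAA", "AAAG", "GAGA", "GAGG")
  # col1 A,A,G,G informative; col2 constant; col3 A,A,G,G informative;
  # col4 A,G,A,G informative
  expect_equal(informative_sites(aln), c(1L, 3L, 4L))
  # singleton columns are excluded
  aln2 <- mk_aln("A", "A", "A", "G")
  expect_length(informative_sites(aln2), 0L)
  # missing data removes sequences from the column
  aln3 <- mk_aln("A-", "A-", "GN", "GA")
  expect_equal(informative_sites(aln3), 1L)   # col2 has < 4 non-missing
  aln4 <- mk_aln("AA", "AA", "GG", "-G")
  expect_equal(informative_sites(aln4), 2L)   # col1 has < 4 non-missing
})

test_that("site-pair incompatibility reduces to the four-gamete test", {
  aln <- mk_aln("AA", "AA", "GG", "GG")
  expect_equal(site_pair_incompatibility(aln, 1, 2), 0L)
  aln2 <- mk_aln("AA", "AG", "GA", "GG")
  expect_equal(site_pair_incompatibility(aln2, 1, 2), 1L)
  expect_error(site_pair_incompatibility(mk_aln("AA", "AA", "GA", "GA"),
                                         1, 2), "informative")
})

test_that("incompatibility equals the exhaustive tree-enumeration oracle", {
  set.seed(11)
  tested <- 0L
  for (rep in 1:40) {
    n <- sample(4:6, 1)
    ci <- sample(c("A", "G", "T"), n, replace = TRUE)
    cj <- sample(c("A", "G", "C"), n, replace = TRUE)
    aln <- cbind(ci, cj)
    rownames(aln) <- paste0("s", 1:n)
    if (!all(c(1L, 2L) %in% informative_sites(aln))) next
    tested <- tested + 1L
    expect_equal(site_pair_incompatibility(aln, 1, 2),
                 brute_pair_incompat(ci, cj))
    # symmetry
    expect_equal(site_pair_incompatibility(aln, 2, 1),
                 site_pair_incompatibility(aln, 1, 2))
  }
  expect_gte(tested, 10L)
})

test_that("phi statistic is invariant to row order and state relabeling", {
  a <- simulate_alignment(list(list(tree = quartet_ab_cd(), n_sites = 300)),
                          1, seed = 5)
  r0 <- phi_test(a, 20, 200, seed = 9)
  r1 <- phi_test(a[sample(nrow(a)), ], 20, 200, seed = 9)
  expect_equal(r1$phi_observed, r0$phi_observed)
  relab <- chartr("ACGT", "TGCA", apply(a, 1, paste, collapse = ""))
  b <- do.call(rbind, strsplit(relab, ""))
  rownames(b) <- rownames(a)
  expect_equal(phi_test(b, 20, 200, seed = 9)$phi_observed, r0$phi_observed)
})

test_that("phi degenerates correctly: untestable data and all-in-window p = 1", {
  aln <- mk_aln("ACGT", "ACGT", "ACGT", "ACGT")
  r <- phi_test(aln, 10, 100, seed = 1)
  expect_equal(r$status, "untestable")
  expect_true(is.na(r$p_value))
  # window covering every pair makes permutation a no-op
  a <- simulate_alignment(list(list(tree = quartet_ab_cd(), n_sites = 200)),
                          1, seed = 2)
  m <- length(informative_sites(a))
  r2 <- phi_test(a, window_w = m + 10L, n_permutations = 100, seed = 3)
  expect_equal(r2$p_value, 1)
  # bit-for-bit reproducibility given (seed, n_permutations)
  r3 <- phi_test(a, 15, 150, seed = 42)
  r4 <- phi_test(a, 15, 150, seed = 42)
  expect_identical(r3$p_value, r4$p_value)
  expect_gte(r3$p_value, 1 / 151)
})

test_that("the screen applies the strict all-tests rule", {
  res <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    p_value = c(0.005, 0.005, 0.5, NA),
                    status = c("tested", "tested", "tested", "untestable"))
  ext <- data.frame(gene_id = c("g1", "g2"), maxchi = c(0.001, 0.02),
                    nss = c(0.001, 0.001))
  s <- recombination_screen(res, external = ext, alpha = 0.01)
  expect_equal(s$n_tested, 3L)          # untestable gene excluded
  expect_equal(s$n_positive, 1L)        # g2 fails the external MaxChi p
  expect_true(s$verdicts$positive[1])
  expect_false(s$verdicts$positive[2])
  expect_error(recombination_screen(res[c(1, 1), ]), "duplicate")
  expect_error(recombination_screen(res[4, ]), "zero testable")
  expect_error(recombination_screen(res, alpha = 1.2), "alpha")
})

test_that("screen fractions are rounded half away from zero to one decimal", {
  res <- data.frame(gene_id = paste0("g", 1:1053),
                    p_value = c(rep(0.001, 47), rep(0.9, 1006)))
  s <- recombination_screen(res, alpha = 0.01)
  expect_equal(s$n_positive, 47L)
  expect_equal(s$fraction_percent, 4.5)
  # 1/16 = 6.25% rounds up, not to even
  res2 <- data.frame(gene_id = paste0("g", 1:16),
                     p_value = c(0.001, rep(0.9, 15)))
  expect_equal(recombination_screen(res2, alpha = 0.01)$fraction_percent, 6.3)
})
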