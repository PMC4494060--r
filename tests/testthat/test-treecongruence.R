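read_nwk <- function(txt) read_trees(write_tmp(txt, ".nwk"))

test_that("supported sister pairs are strictly-thresholded cherries", {
  tr <- read_nwk("((A:1,B:1)97:1,(C:1,D:1)80:1);")
  prs <- supported_sister_pairs(tr, 95)
  expect_equal(nrow(prs), 1L)
  expect_equal(unname(prs[1, ]), c("A", "B"))
  # boundary: support equal to the threshold does not count
  tr2 <- read_nwk("((A:1,B:1)95:1,C:1);")
  expect_equal(nrow(supported_sister_pairs(tr2, 95)), 0L)
  # caterpillar has a single cherry
  tr3 <- read_nwk("(((A:1,B:1)99:1,C:1)99:1,D:1);")
  prs3 <- supported_sister_pairs(tr3, 95)
  expect_equal(nrow(prs3), 1L)
  expect_equal(unname(prs3[1, ]), c("A", "B"))
  # bipartition mode also accepts a supported split isolating a pair
  prs3b <- supported_sister_pairs(tr3, 95, mode = "bipartition")
  expect_true(nrow(prs3b) >= 1L)
  # missing supports fail the threshold
  tr4 <- read_nwk("((A:1,B:1):1,C:1);")
  expect_equal(nrow(supported_sister_pairs(tr4, 0)), 0L)
})

test_that("sister tallies count trees and flag rare arrangements", {
  ts <- read_trees(write_tmp(rep("((A:1,B:1)99:1,C:1);", 10), ".nwk"),
                   multi = TRUE)
  tly <- tally_sister_support(ts, 95)
  expect_equal(tly$counts["A", "B"], 10L)
  expect_equal(sum(tly$counts), 20L)   # symmetric matrix, one pair
  # mixture with no rare pairs at 1%
  mix <- read_trees(write_tmp(c(rep("((A:1,B:1)99:1,C:1);", 7),
                                rep("((A:1,C:1)99:1,B:1);", 3)), ".nwk"),
                    multi = TRUE)
  t2 <- tally_sister_support(mix, 95, rare_fraction = 0.01)
  expect_equal(t2$counts["A", "B"], 7L)
  expect_equal(t2$counts["A", "C"], 3L)
  expect_equal(nrow(t2$rare_pairs), 0L)
  # at 50% the minority arrangement is rare
  t3 <- tally_sister_support(mix, 95, rare_fraction = 0.5)
  expect_equal(nrow(t3$rare_pairs), 1L)
  expect_error(tally_sister_support(structure(list(), class = "multiPhylo")),
               "empty")
})

test_that("tally totals are bounded by trees times cherries", {
  gt <- simulate_gene_trees(kunkeei_like_tree(), 50, support_mean = 90,
                            support_sd = 10, seed = 4)
  tly <- tally_sister_support(gt, 80)
  n_leaves <- length(tly$taxa)
  expect_lte(sum(tly$counts) / 2, tly$n_trees * floor(n_leaves / 2))
})

test_that("sister pairs away from the root survive re-rooting", {
  tr <- read_nwk("(((A:1,B:1)99:1,(C:1,D:1)99:1)99:1,(E:1,F:1)99:1);")
  base <- supported_sister_pairs(tr, 95)
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  for (og in c("A", "C", "E")) {
    rr <- ape::root(tr, outgroup = og, resolve.root = TRUE,
                    edgelabel = TRUE)
    rr <- archflux:::.normalize_supports(rr)
    prs <- supported_sister_pairs(rr, 95)
    # pairs not involving the re-rooted edge are retained
    shared <- intersect(key(base), key(prs))
    expect_gte(length(shared), 2L)
  }
})

test_that("monophyly support requires every multi-member group as a clade", {
  groups <- list(A = c("A1", "A2"), B = c("B1", "B2"))
  t_yes <- read_nwk("((A1:1,A2:1)99:1,(B1:1,B2:1)99:1);")
  t_low <- read_nwk("((A1:1,A2:1)99:1,(B1:1,B2:1)90:1);")
  t_para <- read_nwk("((A1:1,B1:1)99:1,(A2:1,B2:1)99:1);")
  ts <- c(t_yes, t_low, t_para)
  class(ts) <- "multiPhylo"
  rep <- monophyly_support(ts, groups, threshold = 95)
  expect_equal(rep$per_tree, c(TRUE, FALSE, FALSE))
  expect_equal(rep$n_support, 1L)
  # singleton groups are vacuous
  rep2 <- monophyly_support(c(t_yes), c(groups, list(S = "A1x")),
                            threshold = 95)
  expect_true(rep2$per_tree)
  expect_error(monophyly_support(ts, list(A = c("A1"), B = c("A1", "B1"))),
               "overlap")
})

test_that("monophyly at threshold 0 on fully supported trees equals plain clade checks", {
  set.seed(12)
  for (i in 1:10) {
    tr <- ape::rtree(8)
    tr$node.label <- rep("100", tr$Nnode)
    tr <- archflux:::.normalize_supports(tr)
    grp <- list(g = sample(tr$tip.label, 3))
    ts <- c(tr); class(ts) <- "multiPhylo"
    mine <- monophyly_support(ts, grp, threshold = 0)$per_tree
    oracle <- ape::is.monophyletic(tr, grp$g)
    expect_equal(unname(mine), oracle)
  }
})

test_that("host congruence measures Robinson-Foulds agreement", {
  b <- read_nwk("((s1:1,s2:1):1,(s3:1,s4:1):1);")
  h_same <- read_nwk("((h1:1,h2:1):1,(h3:1,h4:1):1);")
  h_diff <- read_nwk("((h1:1,h3:1):1,(h2:1,h4:1):1);")
  map <- data.frame(bact = paste0("s", 1:4), host = paste0("h", 1:4))
  same <- host_congruence(b, h_same, map)
  expect_equal(same$rf_distance, 0)
  expect_equal(same$normalized_rf, 0)
  expect_equal(same$shared_bipartitions, 1)
  diff <- host_congruence(b, h_diff, map)
  expect_equal(diff$rf_distance, 2)
  expect_equal(diff$normalized_rf, 1)
  expect_error(host_congruence(b, h_same, map[1:3, ]), "fewer than 4")
  map_bad <- map
  map_bad$host[2] <- "h1"
  expect_error(host_congruence(b, h_same, map_bad), "injective")
})

test_that("random tree pairs are nearly maximally distant at n = 10", {
  set.seed(77)
  nrf <- vapply(1:300, function(i) {
    a <- ape::rtree(10)
    b <- ape::rtree(10)
    b$tip.label <- a$tip.label[sample(10)]
    host_congruence(a, b, setNames(a$tip.label, a$tip.label))$normalized_rf
  }, numeric(1))
  expect_gt(mean(nrf), 0.9)
})

test_that("a tree is fully congruent with itself", {
  set.seed(3)
  for (i in 1:5) {
    tr <- ape::rtree(7)
    expect_equal(host_congruence(tr, tr,
                                 setNames(tr$tip.label,
                                          tr$tip.label))$rf_distance, 0)
  }
})
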