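test_that("GC skew takes its defining values on simple windows", {
  # one window covering the whole sequence
  expect_equal(gc_skew_profile(tiny_genome("GGCC", 0, 2), 4, 4)$skew, 0)
  expect_equal(gc_skew_profile(tiny_genome("GGGG", 0, 2), 4, 4)$skew, 1)
  # windows without G or C are flagged and set to 0
  p <- gc_skew_profile(tiny_genome("AATT", 0, 2), 4, 4)
  expect_equal(p$skew, 0)
  expect_true(p$zero_gc)
  expect_error(gc_skew_profile(tiny_genome("ACGT", 0, 2), 0, 1), "> 0")
  expect_error(gc_skew_profile(tiny_genome("ACGT", 0, 2), 8, 1), "exceeds")
})

test_that("reverse complement flips the sign of every window skew", {
  g <- simulate_genome(20000, 0, 10000, 0.2, seed = 3)
  rc <- paste(rev(chartr("ACGT", "TGCA",
                         strsplit(g$sequence, "")[[1]])), collapse = "")
  grc <- circular_genome("rc", g$length, 0, 10000, sequence = rc)
  w <- 2000L
  a <- gc_skew_profile(g, w, w)$skew
  b <- gc_skew_profile(grc, w, w)$skew
  expect_equal(b, -rev(a), tolerance = 1e-12)
})

test_that("cumulative skew is the running sum and ori/ter sit at its extrema", {
  g <- simulate_genome(100000, 20000, 70000, 0.1, seed = 11)
  p <- gc_skew_profile(g, 10000, 1000)
  expect_equal(p$cumulative, cumsum(p$skew))
  ot <- detect_ori_ter(p)
  expect_lte(min(abs(ot$ori - 20000), g$length - abs(ot$ori - 20000)),
             p$window)
  expect_lte(min(abs(ot$ter - 70000), g$length - abs(ot$ter - 70000)),
             p$window)
  # invariance to an additive constant on the cumulative curve: shifting all
  # skews equally shifts cumsum linearly, so compare against polarity flip
  ot2 <- detect_ori_ter(p, polarity = "c_leading")
  expect_equal(sort(c(ot2$ori, ot2$ter)), sort(c(ot$ori, ot$ter)))
})

test_that("a signal-free genome yields no replichore call", {
  g <- simulate_genome(100000, 0, 50000, 0, seed = 21)
  p <- gc_skew_profile(g, 10000, 1000)
  expect_error(detect_ori_ter(p), "no replichore signal")
})

test_that("dif-site scan is IUPAC-aware, double-stranded and circular", {
  g <- tiny_genome(paste0("ACGT", strrep("A", 20)), 0, 12)
  hits <- find_dif_sites(g, "ACGT")
  expect_equal(hits$position, c(0L, 0L))        # palindrome: both strands
  expect_setequal(hits$strand, c("+", "-"))
  # reverse-strand-only motif
  g2 <- tiny_genome(paste0("GGTTTCCA", strrep("T", 16)), 0, 12)
  h2 <- find_dif_sites(g2, "TGGAAA")
  expect_equal(h2$strand, "-")
  expect_equal(h2$position, 2L)
  # N wildcard
  g3 <- tiny_genome(paste0("ACGTGGAAGT", strrep("C", 14)), 0, 12)
  h3 <- find_dif_sites(g3, "ANGT")
  expect_true(all(c(0L, 6L) %in% h3$position[h3$strand == "+"]))
  expect_true(all(h3$mismatches == 0L))
  # circular wrap: motif split across the origin
  g4 <- tiny_genome(paste0("GT", strrep("C", 20), "CA"), 0, 12)
  h4 <- find_dif_sites(g4, "CAGT")
  expect_true(22L %in% h4$position)
  expect_error(find_dif_sites(g, "ACZT"), "IUPAC")
})

test_that("distance to ori follows the circular minimum rule", {
  gm <- circular_genome("g", 1000000, ori = 0, ter = 500000)
  gene_at <- function(mid) gene_table("x", "g", mid - 5L, mid + 5L, "+")
  expect_equal(distance_to_ori(gene_at(750000L), gm), 250000L)
  expect_equal(distance_to_ori(gene_at(500000L), gm), 500000L)  # antipode
  g0 <- gene_table("x", "g", 999995L, 5L, "+")                  # wraps ori
  expect_equal(distance_to_ori(g0, gm), 0L)
})

test_that("distance to ori is invariant under coordinate rotation", {
  L <- 100000L
  set.seed(5)
  starts <- sample(0:(L - 1L), 50)
  genes <- gene_table(paste0("g", 1:50), "g", starts,
                      (starts + 900L) %% L, "+")
  genes$wraps <- genes$start > genes$end
  gm <- circular_genome("g", L, ori = 12345, ter = 62345)
  d0 <- distance_to_ori(genes, gm)
  for (rot in c(1L, 9999L, 54321L)) {
    g2 <- genes
    g2$start <- (genes$start + rot) %% L
    g2$end <- (genes$end + rot) %% L
    g2$wraps <- g2$start > g2$end
    gm2 <- circular_genome("g", L, ori = (12345 + rot) %% L,
                           ter = (62345 + rot) %% L)
    expect_equal(distance_to_ori(g2, gm2), d0)
  }
})

test_that("doubling time is log(2) over the log-linear slope", {
  t <- seq(0, 600, by = 30)
  od <- 0.1 * 2^(t / 55)
  fit <- estimate_doubling_time(t, od)
  expect_equal(fit$doubling_time, 55, tolerance = 1e-6)
  expect_error(estimate_doubling_time(t, rep(0.3, length(t))), "no growth")
  # noisy recovery within 10% over 100 seeds
  err <- vapply(1:100, function(s) {
    gc <- simulate_growth_curve(55, 600, 30, noise_sd = 0.02, seed = s)
    abs(estimate_doubling_time(gc$time_min, gc$od)$doubling_time - 55) / 55
  }, numeric(1))
  expect_lt(max(err), 0.10)
  # plateau-only curve
  gc <- simulate_growth_curve(55, 300, 30, seed = 1, od0 = 0.5,
                              plateau = 0.5)
  expect_error(estimate_doubling_time(gc$time_min, gc$od), "no growth")
  # lag + exponential + plateau: the exponential phase is found
  gc2 <- simulate_growth_curve(40, 900, 30, noise_sd = 0.01, seed = 2,
                               lag = 120, plateau = 1.5)
  fit2 <- estimate_doubling_time(gc2$time_min, gc2$od)
  expect_lt(abs(fit2$doubling_time - 40) / 40, 0.15)
})

test_that("replication ratio R is (L/2/speed)/doubling and scales inversely", {
  r <- replication_ratio_R(1500000, 1000, 55)
  expect_equal(r$R_2dp, 0.23)
  # doubling time equal to replichore time gives exactly 1
  expect_equal(replication_ratio_R(1200000, 1000, 10)$R, 1)
  # halving the doubling time doubles R; doubling speed halves R
  expect_equal(replication_ratio_R(1500000, 1000, 27.5)$R, 2 * r$R)
  expect_equal(replication_ratio_R(1500000, 2000, 55)$R, r$R / 2)
  expect_error(replication_ratio_R(0, 1000, 55), "positive")
})
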