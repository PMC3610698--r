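test_that("MA conversion follows the printed formulas and inverts", {
  expect_equal(compute_ma(10, 4), list(M = 6, A = 7))
  expect_equal(compute_ma(5.5, 5.5), list(M = 0, A = 5.5))
  # algebraic inversion: cy5 = A + M/2, cy3 = A - M/2
  set.seed(1)
  cy5 <- rnorm(50, 10); cy3 <- rnorm(50, 10)
  ma <- compute_ma(cy5, cy3)
  expect_equal(ma$A + ma$M / 2, cy5)
  expect_equal(ma$A - ma$M / 2, cy3)
  # non-finite input propagates invalidity
  ma <- compute_ma(c(1, NA, Inf), c(1, 1, 1))
  expect_true(all(is.na(ma$M[2:3])))
})

test_that("stage transitions are enforced in pipeline order", {
  ann <- small_annotation(n_promoters = 10, n_chromosomes = 1)
  hyb <- simulate_hybridizations(ann, seed = 1)
  ma <- ma_from_hyb(hyb)
  expect_error(aquantile_across_arrays(ma), "loess-stage")
  expect_error(window_median_smooth(ma), "aquantile-stage")
  lo <- gc_group_loess(ma)
  expect_error(gc_group_loess(lo), "raw-stage")
  expect_error(probe_z_scores(lo), "smoothed-stage")
})

test_that("gc-grouped loess removes a planted intensity/GC bias", {
  ann <- generate_genome(n_chromosomes = 1, chrom_length_bp = 10e6,
                         n_promoters = 120, seed = 21)
  hyb <- simulate_hybridizations(ann, truth = NULL, noise_sd = 0.3,
                                 dye_bias_amplitude = 1, seed = 21)
  ma <- gc_group_loess(ma_from_hyb(hyb))
  grp <- medipdmr:::gc_groups(ann$probes$gc, 10)
  for (lev in unique(grp)) {
    i <- grp == lev
    expect_lt(abs(mean(ma$M[i, 1])), 0.05)
  }
})

test_that("bias-free profiles pass through loess nearly unchanged", {
  ann <- generate_genome(seed = 22)
  hyb <- simulate_hybridizations(ann, truth = NULL, noise_sd = 0.3,
                                 dye_bias_amplitude = 0, seed = 22)
  ma <- ma_from_hyb(hyb)
  out <- gc_group_loess(ma, n_groups = 1)
  chg <- abs(out$M[, 1] - ma$M[, 1])
  # the fit of pure noise is negligible where data are dense; boundary
  # points (sparse A tails) carry higher fit variance but stay below the
  # noise scale
  interior <- ma$A[, 1] > quantile(ma$A[, 1], 0.005) &
    ma$A[, 1] < quantile(ma$A[, 1], 0.995)
  expect_lt(max(chg[interior]), 0.05)
  expect_lt(max(chg), 0.3)
  expect_identical(out$A, ma$A)  # A untouched
})

test_that("degenerate GC group with identical A falls back to median M", {
  probes <- data.frame(probe_id = sprintf("p%d", 1:300), chrom = "chr1",
                       start = seq(0, by = 100, length.out = 300),
                       end = seq(60, by = 100, length.out = 300),
                       gc = rep(c(0.3, 0.7), each = 150), gene = "G")
  M <- matrix(rep(c(1, 3), each = 150) + rep(c(0, 0.5), 150), ncol = 1)
  A <- matrix(c(rep(10, 150), rnorm(150, 10)), ncol = 1)
  ma <- ma_set(probes, M, A)
  out <- gc_group_loess(ma, n_groups = 2, min_group_size = 10)
  # group 1 (identical A): correction = median of its M values
  i <- probes$gc == 0.3
  expect_equal(out$M[i, 1], M[i, 1] - median(M[i, 1]))
})

test_that("small GC groups fall back to the pooled curve", {
  set.seed(3)
  n <- 500
  probes <- data.frame(probe_id = sprintf("p%d", 1:n), chrom = "chr1",
                       start = seq(0, by = 100, length.out = n),
                       end = seq(60, by = 100, length.out = n),
                       gc = c(rep(0.4, n - 1), 0.9), gene = "G")
  A <- matrix(rnorm(n, 10), ncol = 1)
  M <- matrix(0.5 * (A - 10) + rnorm(n, 0, 0.1), ncol = 1)
  ma <- ma_set(probes, M, A)
  out <- gc_group_loess(ma, n_groups = 2, min_group_size = 50)
  pooled_only <- gc_group_loess(ma, n_groups = 1)
  # the lone high-GC probe gets exactly the pooled-curve correction
  expect_equal(out$M[n, 1], pooled_only$M[n, 1])
})

test_that("A-quantile equalizes A across arrays and preserves M", {
  probes <- data.frame(probe_id = c("a", "b", "c"), chrom = "chr1",
                       start = c(0, 100, 200), end = c(60, 160, 260),
                       gc = 0.4, gene = "G")
  M <- cbind(c(0.1, -0.2, 0.3), c(1, 2, 3))
  A <- cbind(c(1, 2, 3), c(3, 4, 5))
  ma <- ma_set(probes, M, A, stage = "loess")
  out <- aquantile_across_arrays(ma)
  # rank-mean oracle: both arrays become (2,3,4) on the ranked probes
  expect_equal(out$A, cbind(c(2, 3, 4), c(2, 3, 4)))
  expect_equal(out$M, M)

  # fixed point: identical arrays pass through unchanged
  ma2 <- ma_set(probes, M, cbind(c(1, 2, 3), c(1, 2, 3)), stage = "loess")
  out2 <- aquantile_across_arrays(ma2)
  expect_equal(out2$A, ma2$A)

  # defining property on random data: sorted A vectors agree across arrays
  set.seed(4)
  n <- 200
  probes_n <- data.frame(probe_id = sprintf("p%d", 1:n), chrom = "chr1",
                         start = seq(0, by = 100, length.out = n),
                         end = seq(60, by = 100, length.out = n),
                         gc = 0.4, gene = "G")
  ma3 <- ma_set(probes_n, matrix(rnorm(3 * n), n),
                matrix(rnorm(3 * n, 10), n), stage = "loess")
  out3 <- aquantile_across_arrays(ma3)
  s <- apply(out3$A, 2, sort)
  expect_equal(s[, 2], s[, 1])
  expect_equal(s[, 3], s[, 1])
})

test_that("window median smoothing matches the brute-force oracle", {
  ann <- small_annotation(n_promoters = 20, n_chromosomes = 2)
  hyb <- simulate_hybridizations(ann, seed = 12)
  ma <- aquantile_across_arrays(gc_group_loess(ma_from_hyb(hyb)))
  for (pool in c(TRUE, FALSE)) {
    sm <- window_median_smooth(ma, pool_arrays = pool)
    oracle <- brute_window_median(ma$probes, ma$M, ma$A, pool_arrays = pool)
    expect_equal(unname(sm$M), oracle$M)
    expect_equal(unname(sm$A), oracle$A)
    expect_equal(sm$valid, oracle$valid)
  }
})

test_that("windowed median follows the printed 600 bp / 3-probe rule", {
  mk <- function(mids, M) {
    n <- length(mids)
    probes <- data.frame(probe_id = sprintf("p%d", 1:n), chrom = "chr1",
                         start = mids - 30, end = mids + 30, gc = 0.4,
                         gene = "G")
    ma_set(probes, matrix(M, ncol = 1), matrix(10, n, 1),
           stage = "aquantile")
  }
  out <- window_median_smooth(mk(c(100, 200, 300), c(1, 5, 9)))
  expect_equal(out$M[2, 1], 5)  # median{1,5,9}
  # constants are a fixed point of the median
  outc <- window_median_smooth(mk(c(100, 200, 300, 400), rep(2.5, 4)))
  expect_true(all(outc$M[outc$valid, 1] == 2.5))
  # isolated probe with only 2 probes in its window: no value assigned
  out2 <- window_median_smooth(mk(c(100, 200, 300, 5000, 5100), c(1, 2, 3, 4, 5)))
  expect_false(any(out2$valid[4:5]))
  expect_true(all(is.na(out2$M[4:5, 1])))
  expect_true(all(out2$valid[1:3]))
})

test_that("min_probes counts distinct genomic positions, not measurements", {
  # two probes 100 bp apart, three arrays: pooling arrays gives 6
  # measurements but only 2 positions -> still invalid at min_probes = 3
  probes <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                       start = c(100, 200), end = c(160, 260), gc = 0.4,
                       gene = "G")
  ma <- ma_set(probes, matrix(1, 2, 3), matrix(10, 2, 3),
               stage = "aquantile")
  out <- window_median_smooth(ma, pool_arrays = TRUE)
  expect_false(any(out$valid))
})

test_that("smoothing demands sorted probes and preserves count and order", {
  probes <- data.frame(probe_id = c("b", "a"), chrom = "chr1",
                       start = c(200, 100), end = c(260, 160), gc = 0.4,
                       gene = "G")
  ma <- ma_set(probes, matrix(1, 2, 1), matrix(10, 2, 1),
               stage = "aquantile")
  expect_error(window_median_smooth(ma), "sorted")

  ann <- small_annotation(n_promoters = 10, n_chromosomes = 1)
  hyb <- simulate_hybridizations(ann, seed = 5)
  sm <- normalize_chain(hyb)
  expect_identical(sm$probes, ann$probes)  # never reorders or drops probes
})

test_that("each normalization stage is idempotent on its own output", {
  ann <- small_annotation(n_promoters = 120, chrom_length_bp = 4e6,
                          n_chromosomes = 1)
  hyb <- simulate_hybridizations(ann, dye_bias_amplitude = 1, seed = 13)
  lo <- gc_group_loess(ma_from_hyb(hyb), n_groups = 1)
  lo2 <- gc_group_loess(ma_set(lo$probes, lo$M, lo$A, stage = "raw",
                               valid = lo$valid), n_groups = 1)
  expect_lt(max(abs(lo2$M - lo$M)), 0.05)
  aq <- aquantile_across_arrays(lo)
  aq2 <- aquantile_across_arrays(ma_set(aq$probes, aq$M, aq$A,
                                        stage = "loess", valid = aq$valid))
  expect_equal(aq2$A, aq$A, tolerance = 1e-12)
  # median smoothing: piecewise-constant (pooled-smoothed) data is a fixed
  # point up to window-membership effects on constant stretches
  const <- ma_set(aq$probes, matrix(1.5, nrow(aq$M), ncol(aq$M)),
                  matrix(10, nrow(aq$M), ncol(aq$M)), stage = "aquantile",
                  valid = aq$valid)
  sm <- window_median_smooth(const)
  expect_true(all(sm$M[sm$valid, ] == 1.5))
})
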