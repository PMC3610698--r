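# builds a smoothed-stage ma_set directly from given M values
smoothed_set <- function(M, mids = NULL, A = NULL, chrom = "chr1") {
  n <- nrow(M)
  if (is.null(mids)) mids <- seq(100, by = 100, length.out = n)
  probes <- data.frame(probe_id = sprintf("p%03d", seq_len(n)),
                       chrom = chrom, start = mids - 30, end = mids + 30,
                       gc = 0.4, gene = "G", stringsAsFactors = FALSE)
  if (is.null(A)) A <- matrix(10, n, ncol(M))
  ma_set(probes, M, A, stage = "smoothed")
}

test_that("probe z-scores follow the empirical normal scaling", {
  set.seed(10)
  m <- rnorm(5000)
  mu <- mean(m); sg <- sd(m)
  m[1] <- mu + 3 * sg                   # plant a probe exactly at +3 sd
  ma <- smoothed_set(cbind(m))
  ps <- probe_z_scores(ma)
  # recompute against the normal CDF oracle (moments shift slightly after
  # planting, so compare to the freshly computed moments)
  mu2 <- mean(m); sg2 <- sd(m)
  expect_equal(unname(ps$z[1, 1]), (m[1] - mu2) / sg2, tolerance = 1e-12)
  expect_equal(unname(ps$p[1, 1]), 2 * (1 - pnorm(abs(unname(ps$z[1, 1])))), tolerance = 1e-12)
  expect_equal(unname(ps$p[1, 1]), 2 * (1 - pnorm((m[1] - mu2) / sg2)),
               tolerance = 1e-3)
  # probe at the mean: z = 0, p = 1
  m2 <- c(m, mean(m))
  ps2 <- probe_z_scores(smoothed_set(cbind(m2)))
  mu3 <- mean(m2)
  i <- length(m2)
  expect_equal(unname(ps2$z[i, 1]), (m2[i] - mu3) / sd(m2), tolerance = 1e-9)
  expect_lt(abs(unname(ps2$z[i, 1])), 1e-6)
  expect_gt(unname(ps2$p[i, 1]), 0.999)
  # degenerate distribution errors
  expect_error(probe_z_scores(smoothed_set(cbind(rep(1, 10)))),
               "degenerate")
})

test_that("null smoothed profiles produce essentially no significant probes", {
  # a single representative null seed; the 10-seed version runs in the
  # acceptance suite
  ann <- generate_genome(seed = 31)
  hyb <- simulate_hybridizations(ann, truth = NULL, dye_bias_amplitude = 1,
                                 seed = 31)
  sm <- normalize_chain(hyb)
  ps <- probe_z_scores(sm, threshold = 1e-5)
  expect_lte(sum(ps$sig[, 1]), 1)
})

test_that("paired intersection retains only all-pairs-significant probes", {
  sig <- rbind(c(TRUE, TRUE, FALSE),   # pair (1,2) only
               c(TRUE, TRUE, TRUE),    # all pairs and final set
               c(FALSE, TRUE, TRUE),
               c(FALSE, FALSE, FALSE))
  ps <- structure(list(sig = sig, probes = data.frame(probe_id = 1:4),
                       p = matrix(0.5, 4, 3), M = matrix(0, 4, 3),
                       A = matrix(10, 4, 3), valid = rep(TRUE, 4),
                       threshold = 1e-5), class = "probe_significance")
  colnames(ps$sig) <- paste0("h", 1:3)
  pi <- paired_intersection(ps)
  expect_equal(unname(pi$pair_sizes), c(2L, 1L, 2L))
  expect_equal(pi$retained, c(FALSE, TRUE, FALSE, FALSE))
  expect_lte(sum(pi$retained), min(pi$pair_sizes))
  ps1 <- ps; ps1$sig <- ps$sig[, 1, drop = FALSE]
  expect_error(paired_intersection(ps1), "at least two")
})

test_that("intersection of all pairs equals intersection of all singles", {
  set.seed(5)
  for (rep in 1:20) {
    H <- sample(2:5, 1)
    sig <- matrix(runif(50 * H) < 0.3, 50, H)
    colnames(sig) <- paste0("h", seq_len(H))
    ps <- structure(list(sig = sig, probes = data.frame(probe_id = 1:50),
                         p = matrix(0.5, 50, H), M = matrix(0, 50, H),
                         A = matrix(10, 50, H), valid = rep(TRUE, 50),
                         threshold = 1e-5), class = "probe_significance")
    pi <- paired_intersection(ps)
    expect_equal(pi$retained, rowSums(sig) == H)
    # adding a hybridization never grows the intersection
    sig2 <- cbind(sig, runif(50) < 0.3)
    colnames(sig2) <- paste0("h", seq_len(H + 1))
    ps2 <- ps; ps2$sig <- sig2
    expect_true(all(paired_intersection(ps2)$retained <= pi$retained))
  }
})

test_that("raising the p threshold never shrinks the significant set", {
  set.seed(6)
  ma <- smoothed_set(cbind(rnorm(2000), rnorm(2000), rnorm(2000)))
  ps_strict <- probe_z_scores(ma, threshold = 1e-3)
  ps_loose <- probe_z_scores(ma, threshold = 1e-2)
  expect_true(all(ps_loose$sig >= ps_strict$sig))
})

test_that("probes cluster by the 600-base gap and mean-M sign rules", {
  ma <- smoothed_set(cbind(c(1, 1, 1), c(1, 1, 1)),
                     mids = c(1000, 1400, 2300))
  ps <- structure(list(sig = matrix(TRUE, 3, 2), probes = ma$probes,
                       p = matrix(1e-6, 3, 2), M = ma$M, A = ma$A,
                       valid = rep(TRUE, 3), threshold = 1e-5),
                  class = "probe_significance")
  regions <- cluster_probes_to_regions(ps, rep(TRUE, 3))
  expect_equal(nrow(regions), 2)  # 2300 - 1400 > 600 splits
  expect_equal(regions$n_probes, c(2L, 1L))

  # sign split: adjacent probes with opposite mean M
  ma2 <- smoothed_set(cbind(c(1, -1)), mids = c(1000, 1200))
  ps2 <- structure(list(sig = matrix(TRUE, 2, 1),
                        probes = ma2$probes, p = matrix(1e-6, 2, 1),
                        M = ma2$M, A = ma2$A, valid = c(TRUE, TRUE),
                        threshold = 1e-5), class = "probe_significance")
  r2 <- cluster_probes_to_regions(ps2, c(TRUE, TRUE))
  expect_equal(nrow(r2), 2)
  expect_equal(r2$direction, c(1L, -1L))
  expect_equal(r2$n_probes, c(1L, 1L))

  # region p-value is the least favorable member p; interval spans probes
  p <- matrix(c(1e-8, 1e-6, 1e-7), 3, 1)
  ps3 <- structure(list(sig = matrix(TRUE, 3, 1),
                        probes = smoothed_set(cbind(c(1, 1, 1)))$probes,
                        p = p, M = matrix(1, 3, 1), A = matrix(10, 3, 1),
                        valid = rep(TRUE, 3), threshold = 1e-5),
                   class = "probe_significance")
  r3 <- cluster_probes_to_regions(ps3, rep(TRUE, 3))
  expect_equal(r3$p_value, 1e-6)
  expect_equal(r3$start, 70)      # first probe start
  expect_equal(r3$end, 330)       # last probe end

  # exact-zero mean M is assigned +1 with a message
  ps4 <- ps2; ps4$M <- matrix(c(0, 0), 2, 1)
  expect_message(r4 <- cluster_probes_to_regions(ps4, c(TRUE, TRUE)),
                 "exactly 0")
  expect_equal(r4$direction, 1L)
})

test_that("region filters apply the printed intensity and density rules", {
  regions <- data.frame(chrom = "chr1",
                        start = c(0, 0, 0), end = c(600, 600, 300),
                        mean_A = c(9.4, 10, 10),
                        n_cpg = c(6, 6, 2),
                        cpg_density = c(1, 100 * 6 / 600, 100 * 2 / 300))
  out <- suppressMessages(filter_regions(regions))
  # mean A 9.4 removed ("exceeding 9.5" is strict); density 1.0 kept
  # (boundary inclusive); density 0.667 removed
  expect_equal(nrow(out), 1)
  expect_equal(out$mean_A, 10)
  expect_equal(out$cpg_density, 1)
  removed <- attr(out, "removed")
  expect_setequal(removed$failed, c("mean_A", "cpg_density"))
  # boundary: mean A exactly 9.5 is not "exceeding"
  r95 <- data.frame(chrom = "chr1", start = 0, end = 600, mean_A = 9.5,
                    n_cpg = 6, cpg_density = 1)
  expect_equal(nrow(suppressMessages(filter_regions(r95))), 0)
})

test_that("region annotation assigns promoters and counts CpGs exactly", {
  ann <- small_annotation(n_promoters = 30, n_chromosomes = 1)
  pr <- ann$promoters[order(ann$promoters$start), ]
  g <- pr$gene[3]
  region <- data.frame(chrom = pr$chrom[3], start = pr$start[3] + 100,
                       end = pr$start[3] + 800)
  out <- annotate_regions(region, ann)
  expect_equal(out$gene, g)
  # CpG count equals a linear scan over the planted positions
  pos <- ann$cpg$pos[ann$cpg$chrom == region$chrom]
  brute <- sum(pos >= region$start & pos < region$end)
  expect_equal(out$n_cpg, brute)
  expect_equal(out$cpg_density, 100 * brute / 700)
  # no-overlap region is flagged with NA gene
  far <- data.frame(chrom = pr$chrom[1], start = pr$end[1] + 10,
                    end = pr$end[1] + 20)
  expect_message(out2 <- annotate_regions(far, ann), "no promoter")
  expect_true(is.na(out2$gene))
})

test_that("planted DMRs are recovered as regions covering their probes", {
  ann <- generate_genome(seed = 33)
  truth <- plant_truth(ann, n_dmrs = 8, dmr_probes = c(8, 8),
                       dmr_delta_m = 4 * 0.3, de_background_rate = 0,
                       n_clusters = 0, motif_fraction = 0, seed = 33)
  hyb <- simulate_hybridizations(ann, truth, noise_sd = 0.3,
                                 dye_bias_amplitude = 1, seed = 33)
  sm <- normalize_chain(hyb)
  res <- call_dmrs(sm, ann)
  rec <- score_region_recovery(res$dmrs, truth$dmrs)
  expect_gte(rec$sensitivity, 0.8)
  expect_gte(rec$precision, 0.8)
  # each matched region covers most of its planted probe positions
  for (r in seq_len(nrow(rec$matches))) {
    called <- res$dmrs[rec$matches$a_idx[r], ]
    planted <- truth$dmrs[rec$matches$b_idx[r], ]
    mids <- (ann$probes$start + ann$probes$end) / 2
    pm <- mids[ann$probes$chrom == planted$chrom &
                 mids >= planted$start & mids < planted$end]
    covered <- sum(pm >= called$start & pm <= called$end)
    expect_gte(covered, 6)
    # direction matches the planted effect sign
    expect_equal(called$direction, sign(planted$effect))
  }
})
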