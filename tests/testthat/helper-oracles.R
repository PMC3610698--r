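# Independent brute-force oracles. These deliberately re-derive each
# quantity with naive nested loops / closed forms, never through the
# package's own code path.

# boundary-corrected window center for probe i, computed by naive scans:
# the window is clamped inside the contiguous run of valid probes (gaps
# <= window_bp); runs shorter than the window use the run midpoint
brute_window_center <- function(mid_i, chrom_i, mids, chroms, valid,
                                window_bp) {
  cm <- sort(mids[valid & chroms == chrom_i])
  k <- match(mid_i, cm)
  lo <- k
  while (lo > 1 && cm[lo] - cm[lo - 1] <= window_bp) lo <- lo - 1
  hi <- k
  while (hi < length(cm) && cm[hi + 1] - cm[hi] <= window_bp) hi <- hi + 1
  if (cm[hi] - cm[lo] < window_bp) return((cm[lo] + cm[hi]) / 2)
  min(max(mid_i, cm[lo] + window_bp / 2), cm[hi] - window_bp / 2)
}

# windowed median smoothing by explicit nested loops
brute_window_median <- function(probes, M, A, window_bp = 600,
                                min_probes = 3, pool_arrays = FALSE,
                                valid = rep(TRUE, nrow(probes))) {
  n <- nrow(probes)
  H <- ncol(M)
  mids <- (probes$start + probes$end) / 2
  outM <- matrix(NA_real_, n, H)
  outA <- matrix(NA_real_, n, H)
  out_valid <- logical(n)
  for (i in seq_len(n)) {
    if (!valid[i]) next
    ctr <- brute_window_center(mids[i], probes$chrom[i], mids,
                               probes$chrom, valid, window_bp)
    win <- integer(0)
    for (j in seq_len(n)) {
      if (valid[j] && probes$chrom[j] == probes$chrom[i] &&
          abs(mids[j] - ctr) <= window_bp / 2)
        win <- c(win, j)
    }
    if (length(unique(mids[win])) < min_probes) next
    out_valid[i] <- TRUE
    if (pool_arrays) {
      outM[i, ] <- median(as.vector(M[win, ]))
      outA[i, ] <- median(as.vector(A[win, ]))
    } else {
      for (h in seq_len(H)) {
        outM[i, h] <- median(M[win, h])
        outA[i, h] <- median(A[win, h])
      }
    }
  }
  list(M = outM, A = outA, valid = out_valid)
}

# IUPAC expansion table, written out by hand
iupac_table <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                 D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

naive_revcomp <- function(s) {
  paste(rev(comp_base[strsplit(s, "")[[1]]]), collapse = "")
}

# does consensus match sequence at 1-based offset? N in the sequence only
# matches a consensus position that itself allows N (i.e. is N)
naive_match_at <- function(seq_chars, cons_chars, off) {
  for (k in seq_along(cons_chars)) {
    sc <- seq_chars[off + k - 1]
    allowed <- strsplit(iupac_table[[cons_chars[k]]], "")[[1]]
    if (sc == "N") {
      if (cons_chars[k] != "N") return(FALSE)
    } else if (!(sc %in% allowed)) return(FALSE)
  }
  TRUE
}

# naive both-strand scanner; returns 0-based forward offsets
naive_scan_one <- function(seq, consensus) {
  sc <- strsplit(toupper(seq), "")[[1]]
  cf <- strsplit(consensus, "")[[1]]
  cr <- strsplit(naive_revcomp_iupac(consensus), "")[[1]]
  L <- length(sc); m <- length(cf)
  offs <- integer(0)
  if (L >= m) {
    for (o in seq_len(L - m + 1)) {
      if (naive_match_at(sc, cf, o) || naive_match_at(sc, cr, o))
        offs <- c(offs, o - 1L)
    }
  }
  offs
}

# reverse complement of an IUPAC consensus
iupac_comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                H = "D", V = "B", N = "N")
naive_revcomp_iupac <- function(s) {
  paste(rev(iupac_comp[strsplit(s, "")[[1]]]), collapse = "")
}

# quadratic all-pairs interval overlap
brute_overlap_pairs <- function(a, b, min_overlap = 1) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_overlap)
      out <- rbind(out, data.frame(a_idx = i, b_idx = j, overlap_bp = ov))
  }
  if (is.null(out)) data.frame(a_idx = integer(0), b_idx = integer(0),
                               overlap_bp = numeric(0)) else out
}

# quadratic all-pairs gap distance
brute_assoc_pairs <- function(a, b, max_dist) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    gap <- max(0, max(b$start[j] - a$end[i], a$start[i] - b$end[j]))
    if (gap <= max_dist)
      out <- rbind(out, data.frame(cluster_idx = i, dmr_idx = j,
                                   distance_bp = gap))
  }
  if (is.null(out)) data.frame(cluster_idx = integer(0),
                               dmr_idx = integer(0),
                               distance_bp = numeric(0)) else out
}

# closed-form one-way two-group ANOVA F-test p-value (on log2 signals)
oneway_anova_p <- function(y1, y2) {
  n1 <- length(y1); n2 <- length(y2)
  gm <- mean(c(y1, y2))
  ssb <- n1 * (mean(y1) - gm)^2 + n2 * (mean(y2) - gm)^2
  ssw <- sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)
  f <- (ssb / 1) / (ssw / (n1 + n2 - 2))
  pf(f, 1, n1 + n2 - 2, lower.tail = FALSE)
}

# brute-force re-application of the three DE gates from raw signals,
# using a generic linear-model fit on a freshly built design matrix
brute_de_filter <- function(signals, samples, p_max = 0.05,
                            fold_min = 1.2, diff_min = 10) {
  res <- logical(nrow(signals))
  dirn <- integer(nrow(signals))
  for (g in seq_len(nrow(signals))) {
    y <- log2(signals[g, ])
    tr <- as.integer(samples$treatment == "treated")
    X <- cbind(1, tr)
    if (length(unique(samples$batch)) > 1)
      X <- cbind(X, model.matrix(~ 0 + factor(samples$batch))[, -1, drop = FALSE])
    fit_full <- lm.fit(X, y)
    X0 <- X[, -2, drop = FALSE]
    fit_red <- lm.fit(X0, y)
    rss1 <- sum(fit_full$residuals^2)
    rss0 <- sum(fit_red$residuals^2)
    df2 <- length(y) - ncol(X)
    f <- (rss0 - rss1) / (rss1 / df2)
    p <- pf(f, 1, df2, lower.tail = FALSE)
    mt <- mean(signals[g, samples$treatment == "treated"])
    mc <- mean(signals[g, samples$treatment == "control"])
    fold <- max(mt / mc, mc / mt)
    res[g] <- p < p_max && fold > fold_min && abs(mt - mc) > diff_min
    dirn[g] <- if (mt >= mc) 1L else -1L
  }
  list(selected = res, direction = dirn)
}

# stride arithmetic for sliding windows on one chromosome
brute_window_count <- function(L, window_bp, step_bp) {
  if (L < window_bp) 1L else floor((L - window_bp) / step_bp) + 1L
}

# small fixture: annotation scaled for fast unit tests
small_annotation <- function(seed = 11, n_promoters = 60,
                             chrom_length_bp = 2e6, n_chromosomes = 2) {
  generate_genome(n_chromosomes = n_chromosomes,
                  chrom_length_bp = chrom_length_bp,
                  n_promoters = n_promoters, seed = seed)
}

# run the normalization chain on a hyb_set
normalize_chain <- function(hyb, n_groups = 10, span = 0.4,
                            window_bp = 600, min_probes = 3,
                            pool_arrays = FALSE) {
  ma <- ma_from_hyb(hyb)
  ma <- gc_group_loess(ma, n_groups = n_groups, span = span)
  ma <- aquantile_across_arrays(ma)
  window_median_smooth(ma, window_bp = window_bp, min_probes = min_probes,
                       pool_arrays = pool_arrays)
}
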