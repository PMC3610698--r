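#' MA profiles for a set of comparative hybridizations
#'
#' Container for per-probe (M, A) values across hybridizations, with a
#' stage tag tracking the normalization pipeline
#' (\code{raw -> loess -> aquantile -> smoothed}) and a per-probe validity
#' flag (probes whose 600 bp smoothing window held fewer than the minimum
#' number of probes are invalidated and carry NA values).
#'
#' @param probes Probe table (probe_id, chrom, start, end, gc, gene).
#' @param M,A Numeric matrices, probes x hybridizations.
#' @param stage One of \code{"raw"}, \code{"loess"}, \code{"aquantile"},
#'   \code{"smoothed"}.
#' @param valid Logical vector, one flag per probe.
#' @return An object of class \code{ma_set}.
#' @export
ma_set <- function(probes, M, A, stage = "raw",
                   valid = rep(TRUE, nrow(probes))) {
  stopifnot(is.matrix(M), is.matrix(A), nrow(M) == nrow(probes),
            all(dim(M) == dim(A)), length(valid) == nrow(probes))
  stage <- match.arg(stage, c("raw", "loess", "aquantile", "smoothed"))
  structure(list(probes = probes, M = M, A = A, stage = stage,
                 valid = valid),
            class = "ma_set")
}

#' @export
print.ma_set <- function(x, ...) {
  cat(sprintf("ma_set [%s]: %d probes x %d hybridizations (%d valid probes)\n",
              x$stage, nrow(x$M), ncol(x$M), sum(x$valid)))
  invisible(x)
}

#' Convert two-channel log2 signals to MA values
#'
#' M = Cy5 - Cy3 (the log ratio) and A = (Cy5 + Cy3)/2 (the average log
#' intensity). Vectorized; non-finite inputs yield NA in both outputs.
#'
#' @param cy5,cy3 log2 channel signals (vectors or matrices of equal shape).
#' @return List with components \code{M} and \code{A}.
#' @export
compute_ma <- function(cy5, cy3) {
  bad <- !is.finite(cy5) | !is.finite(cy3)
  M <- cy5 - cy3
  A <- (cy5 + cy3) / 2
  M[bad] <- NA_real_
  A[bad] <- NA_real_
  list(M = M, A = A)
}

#' Build a raw-stage MA profile set from simulated hybridizations
#'
#' @param hyb A \code{hyb_set}.
#' @return An \code{ma_set} at stage \code{"raw"}; probes with non-finite
#'   signals in any hybridization are flagged invalid.
#' @export
ma_from_hyb <- function(hyb) {
  stopifnot(inherits(hyb, "hyb_set"))
  ma <- compute_ma(hyb$cy5, hyb$cy3)
  valid <- rowSums(!is.finite(ma$M)) == 0
  ma_set(hyb$probes, ma$M, ma$A, stage = "raw", valid = valid)
}

#' GC-grouped within-array loess normalization
#'
#' Probes are separated into groups by GC content and each group is loess
#' normalized separately within each hybridization: a loess curve of M on A
#' is fitted per group and subtracted from M, so each GC group receives a
#' normalization curve specific to that group. A is unchanged. The fit is
#' a degree-2 robust (symmetric-family) loess: local quadratics stay
#' unbiased against intensity-dependent curvature in the sparse tails of
#' the A distribution, where local-linear smoothers undercorrect. Groups
#' smaller than \code{min_group_size} fall back to the pooled (all-probe)
#' curve; a group whose A values are (near-)constant falls back to
#' subtracting its median M.
#'
#' @param ma An \code{ma_set} at stage \code{"raw"}.
#' @param n_groups Number of GC groups (quantile bins of gc fraction).
#' @param span Loess span.
#' @param min_group_size Below this size a group uses the pooled curve.
#' @return An \code{ma_set} at stage \code{"loess"}.
#' @export
gc_group_loess <- function(ma, n_groups = 10, span = 0.4,
                           min_group_size = 200) {
  stopifnot(inherits(ma, "ma_set"), n_groups >= 1)
  if (ma$stage != "raw")
    stop("gc_group_loess expects a raw-stage profile, got ", ma$stage)
  gc <- ma$probes$gc
  if (anyNA(gc)) stop("every probe needs a gc fraction")
  grp <- gc_groups(gc, n_groups)

  ma_loess <- function(m, a) {
    # duplicated A values can trigger harmless zero-width-neighborhood
    # warnings; real failures are caught by the callers' fallbacks
    fit <- suppressWarnings(
      stats::loess(m ~ a, span = span, degree = 2, family = "symmetric",
                   control = stats::loess.control(cell = 0.05)))
    m - stats::fitted(fit)
  }
  M <- ma$M
  for (h in seq_len(ncol(M))) {
    ok <- ma$valid & is.finite(ma$M[, h]) & is.finite(ma$A[, h])
    m <- ma$M[ok, h]; a <- ma$A[ok, h]; g <- grp[ok]
    out <- tryCatch(ma_loess(m, a),
                    error = function(e) m - stats::median(m))
    for (lev in unique(g)) {
      i <- which(g == lev)
      if (length(i) < min_group_size) next      # pooled fallback
      if (diff(range(a[i])) < 1e-8) {
        out[i] <- m[i] - stats::median(m[i])    # degenerate fit fallback
        next
      }
      out[i] <- tryCatch(ma_loess(m[i], a[i]),
                         error = function(e) m[i] - stats::median(m[i]))
    }
    M[ok, h] <- out
  }
  ma_set(ma$probes, M, ma$A, stage = "loess", valid = ma$valid)
}

# quantile-bin gc fractions into at most n_groups groups
gc_groups <- function(gc, n_groups) {
  if (n_groups == 1) return(rep(1L, length(gc)))
  br <- unique(stats::quantile(gc, probs = seq(0, 1, length.out = n_groups + 1)))
  if (length(br) < 3) return(rep(1L, length(gc)))
  as.integer(cut(gc, breaks = br, include.lowest = TRUE))
}

#' A-quantile normalization across arrays
#'
#' Forces the distribution of A values to be identical across the
#' hybridizations (each probe's A is replaced by the mean of the A values
#' at its rank across arrays) while leaving every probe's M untouched —
#' the limma "Aquantile" contract, and limma performs the computation.
#'
#' @param ma An \code{ma_set} at stage \code{"loess"} holding all arrays.
#' @return An \code{ma_set} at stage \code{"aquantile"}.
#' @export
aquantile_across_arrays <- function(ma) {
  stopifnot(inherits(ma, "ma_set"))
  if (ma$stage != "loess")
    stop("aquantile_across_arrays expects a loess-stage profile, got ",
         ma$stage)
  if (ncol(ma$A) < 2)
    stop("A-quantile normalization needs at least two arrays")
  obj <- methods::new(methods::getClass("MAList",
                                        where = asNamespace("limma")),
                      list(M = ma$M, A = ma$A))
  out <- limma::normalizeBetweenArrays(obj, method = "Aquantile")
  ma_set(ma$probes, out$M, out$A, stage = "aquantile", valid = ma$valid)
}

#' Windowed median smoothing of M and A
#'
#' Each probe's M value is replaced by the median of all probe M values
#' whose midpoints lie within a 600 bp window around the probe (same
#' chromosome), pooled across all arrays by default or within each array
#' with \code{pool_arrays = FALSE}. A values are smoothed by the same
#' procedure. If fewer than \code{min_probes} distinct probe positions
#' contribute to the window, no value is assigned: the probe is flagged
#' invalid and carries NA downstream. Pooling arrays cannot rescue an
#' isolated probe because positions, not measurements, are counted.
#'
#' Window anchoring is boundary-corrected: within each contiguous run of
#' probes (midpoint gaps at most \code{window_bp}), the window is centered
#' on the probe but clamped so that it stays inside the run, exactly as a
#' boundary-corrected moving window. Probes at the edge of a tiled
#' promoter therefore see as many neighbours as interior probes; without
#' this correction the windowed medians of edge probes carry visibly
#' higher variance than interior ones, and probe Z-scores scaled by a
#' single empirical standard deviation become anticonservative at
#' promoter edges. Runs shorter than the window use the whole run.
#'
#' @param ma An \code{ma_set} at stage \code{"aquantile"}, probes sorted by
#'   (chromosome, start).
#' @param window_bp Full window width (bp).
#' @param min_probes Minimum number of distinct probe positions in the
#'   window for a value to be assigned.
#' @param pool_arrays Pool values across all arrays when taking the median
#'   (default FALSE: each array is smoothed separately so per-hybridization
#'   probe statistics stay non-degenerate; see the package vignette).
#' @return An \code{ma_set} at stage \code{"smoothed"}.
#' @export
window_median_smooth <- function(ma, window_bp = 600, min_probes = 3,
                                 pool_arrays = FALSE) {
  stopifnot(inherits(ma, "ma_set"))
  if (ma$stage != "aquantile")
    stop("window_median_smooth expects an aquantile-stage profile, got ",
         ma$stage)
  pb <- ma$probes
  o <- order(pb$chrom, pb$start)
  if (!identical(o, seq_len(nrow(pb))))
    stop("probes must be sorted by (chromosome, start) before smoothing")
  half <- window_bp / 2
  H <- ncol(ma$M)
  newM <- matrix(NA_real_, nrow(pb), H, dimnames = dimnames(ma$M))
  newA <- newM
  valid <- logical(nrow(pb))

  for (cn in unique(pb$chrom)) {
    idx <- which(pb$chrom == cn)
    mids <- (pb$start[idx] + pb$end[idx]) / 2
    ok <- ma$valid[idx]
    okmids <- mids[ok]
    Mc <- ma$M[idx[ok], , drop = FALSE]
    Ac <- ma$A[idx[ok], , drop = FALSE]
    if (length(okmids) == 0) next
    # contiguous runs of valid probes (midpoint gaps <= window_bp)
    run <- cumsum(c(1L, as.integer(diff(okmids) > window_bp)))
    run_first <- stats::ave(okmids, run, FUN = min)
    run_last <- stats::ave(okmids, run, FUN = max)
    # boundary-corrected window centers for the valid probes
    ctr <- pmin(pmax(okmids, run_first + half), run_last - half)
    short <- (run_last - run_first) < window_bp
    ctr[short] <- (run_first[short] + run_last[short]) / 2
    j1v <- findInterval(ctr - half - 1e-9, okmids) + 1L
    j2v <- findInterval(ctr + half + 1e-9, okmids)
    pos <- match(seq_along(idx), which(ok))   # valid-probe index or NA
    for (t in seq_along(idx)) {
      v <- pos[t]
      if (is.na(v)) next
      win <- j1v[v]:j2v[v]
      if (length(unique(okmids[win])) < min_probes) next
      valid[idx[t]] <- TRUE
      if (pool_arrays) {
        newM[idx[t], ] <- stats::median(Mc[win, ], na.rm = TRUE)
        newA[idx[t], ] <- stats::median(Ac[win, ], na.rm = TRUE)
      } else {
        for (h in seq_len(H)) {
          newM[idx[t], h] <- stats::median(Mc[win, h], na.rm = TRUE)
          newA[idx[t], h] <- stats::median(Ac[win, h], na.rm = TRUE)
        }
      }
    }
  }
  ma_set(pb, newM, newA, stage = "smoothed", valid = valid)
}
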