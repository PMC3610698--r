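#' Score recovery of planted regions
#'
#' Matches called regions against planted regions by reciprocal interval
#' overlap: a pair matches when the overlap covers at least
#' \code{min_reciprocal} of both intervals. Sensitivity is the fraction of
#' planted regions matched; precision the fraction of called regions
#' matched.
#'
#' @param called,planted Region data frames (chrom, start, end).
#' @param min_reciprocal Minimum reciprocal overlap fraction (default 0.5).
#' @return List with sensitivity, precision, n_called, n_planted and the
#'   match pair table.
#' @export
score_region_recovery <- function(called, planted, min_reciprocal = 0.5) {
  if (nrow(planted) == 0)
    return(list(sensitivity = NA_real_,
                precision = if (nrow(called)) 0 else NA_real_,
                n_called = nrow(called), n_planted = 0,
                matches = data.frame()))
  if (nrow(called) == 0)
    return(list(sensitivity = 0, precision = NA_real_, n_called = 0,
                n_planted = nrow(planted), matches = data.frame()))
  pairs <- overlap_dmr_sets(called, planted)
  if (nrow(pairs)) {
    frac_a <- pairs$overlap_bp /
      (called$end[pairs$a_idx] - called$start[pairs$a_idx])
    frac_b <- pairs$overlap_bp /
      (planted$end[pairs$b_idx] - planted$start[pairs$b_idx])
    pairs <- pairs[frac_a >= min_reciprocal & frac_b >= min_reciprocal, ,
                   drop = FALSE]
  }
  list(sensitivity = length(unique(pairs$b_idx)) / nrow(planted),
       precision = length(unique(pairs$a_idx)) / nrow(called),
       n_called = nrow(called), n_planted = nrow(planted),
       matches = pairs)
}

#' Fraction of a planted interval covered by called clusters
#'
#' Used to score ECR cluster recovery: for each planted interval, the
#' fraction of its length covered by the union of called cluster
#' intervals on the same chromosome.
#'
#' @param clusters,planted Region data frames (chrom, start, end).
#' @return Numeric vector, one coverage fraction per planted interval.
#' @export
interval_coverage <- function(clusters, planted) {
  vapply(seq_len(nrow(planted)), function(i) {
    cl <- clusters[clusters$chrom == planted$chrom[i], , drop = FALSE]
    if (nrow(cl) == 0) return(0)
    s <- pmax(cl$start, planted$start[i])
    e <- pmin(cl$end, planted$end[i])
    keep <- e > s
    if (!any(keep)) return(0)
    ir <- IRanges::reduce(IRanges::IRanges(start = s[keep] + 1, end = e[keep]))
    sum(IRanges::width(ir)) / (planted$end[i] - planted$start[i])
  }, numeric(1))
}
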