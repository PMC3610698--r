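#' Probe-level Z-scores and p-values per comparative hybridization
#'
#' For each hybridization, the smoothed M values of the valid probes are
#' compared to a normal distribution scaled to their empirical mean and
#' standard deviation: z = (M - mu)/sigma, with a two-sided normal tail
#' p-value. A probe is significant in a hybridization when p < threshold.
#'
#' @param ma An \code{ma_set} at stage \code{"smoothed"}.
#' @param threshold Significance threshold on p (default 1e-5).
#' @param pooled_moments Compute mu and sigma pooled over all
#'   hybridizations instead of per hybridization.
#' @return An object of class \code{probe_significance}: list with
#'   \code{probes}, matrices \code{z}, \code{p}, \code{sig}, the smoothed
#'   \code{M} and \code{A}, \code{valid}, and \code{threshold}.
#' @export
probe_z_scores <- function(ma, threshold = 1e-5, pooled_moments = FALSE) {
  stopifnot(inherits(ma, "ma_set"))
  if (ma$stage != "smoothed")
    stop("probe_z_scores expects a smoothed-stage profile, got ", ma$stage)
  if (sum(ma$valid) < 2)
    stop("need at least two valid probes to scale the distribution")
  z <- matrix(NA_real_, nrow(ma$M), ncol(ma$M), dimnames = dimnames(ma$M))
  if (pooled_moments) {
    v <- ma$M[ma$valid, , drop = FALSE]
    mu <- mean(v); sg <- stats::sd(as.vector(v))
    if (!is.finite(sg) || sg == 0)
      stop("degenerate smoothed M distribution: zero standard deviation")
    z[ma$valid, ] <- (ma$M[ma$valid, , drop = FALSE] - mu) / sg
  } else {
    for (h in seq_len(ncol(ma$M))) {
      v <- ma$M[ma$valid, h]
      mu <- mean(v); sg <- stats::sd(v)
      if (!is.finite(sg) || sg == 0)
        stop("degenerate smoothed M distribution: zero standard deviation")
      z[ma$valid, h] <- (ma$M[ma$valid, h] - mu) / sg
    }
  }
  p <- 2 * stats::pnorm(-abs(z))
  sig <- p < threshold
  sig[is.na(sig)] <- FALSE
  structure(list(probes = ma$probes, z = z, p = p, sig = sig,
                 M = ma$M, A = ma$A, valid = ma$valid,
                 threshold = threshold),
            class = "probe_significance")
}

#' @export
print.probe_significance <- function(x, ...) {
  cat(sprintf("probe_significance: %d probes x %d hybridizations, p < %g; significant per hyb: %s\n",
              nrow(x$p), ncol(x$p), x$threshold,
              paste(colSums(x$sig), collapse = ", ")))
  invisible(x)
}

#' Intersect probe significance across paired comparisons
#'
#' The statistical analysis is performed in pairs of comparative
#' hybridizations: for each unordered pair (i, j) a probe is
#' pair-significant iff it is significant in both, and the retained set is
#' the intersection over all pairs — equivalently, the probes significant
#' in every hybridization. Pairwise set sizes are reported alongside.
#'
#' @param ps A \code{probe_significance} over >= 2 hybridizations.
#' @return List with \code{retained} (logical per probe), \code{pair_sizes}
#'   (named integer vector, one entry per unordered pair) and \code{pairs}
#'   (2 x n matrix of column indices).
#' @export
paired_intersection <- function(ps) {
  stopifnot(inherits(ps, "probe_significance"))
  H <- ncol(ps$sig)
  if (H < 2)
    stop("pairing requires at least two hybridizations")
  prs <- utils::combn(H, 2)
  sizes <- integer(ncol(prs))
  names(sizes) <- apply(prs, 2, function(ij)
    paste(colnames(ps$sig)[ij], collapse = "&"))
  for (k in seq_len(ncol(prs)))
    sizes[k] <- sum(ps$sig[, prs[1, k]] & ps$sig[, prs[2, k]])
  retained <- rowSums(ps$sig) == H
  list(retained = retained, pair_sizes = sizes, pairs = prs)
}

#' Cluster retained probes into candidate DMRs
#'
#' Retained probes are combined into regions by joining consecutive probes
#' within \code{gap_bp} bases of each other (midpoint to midpoint) whose
#' mean M values share the same sign. The region interval spans the first
#' probe's start to the last probe's end; the region p-value is the least
#' favorable (maximum) member-probe p over hybridizations; the direction is
#' the shared sign of the mean M (+1 hyper, -1 hypo; an exact zero is
#' broken toward +1 and logged).
#'
#' @param ps A \code{probe_significance}.
#' @param retained Logical vector of probes to cluster (e.g. from
#'   \code{paired_intersection}).
#' @param gap_bp Maximum midpoint gap joining consecutive probes.
#' @return Data frame of unfiltered regions: chrom, start, end, direction,
#'   p_value, mean_A, n_probes, probe_ids (comma separated).
#' @export
cluster_probes_to_regions <- function(ps, retained, gap_bp = 600) {
  stopifnot(inherits(ps, "probe_significance"),
            length(retained) == nrow(ps$probes))
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = integer(0),
                      p_value = numeric(0), mean_A = numeric(0),
                      n_probes = integer(0), probe_ids = character(0),
                      stringsAsFactors = FALSE)
  idx <- which(retained)
  if (length(idx) == 0) return(empty)
  pb <- ps$probes[idx, , drop = FALSE]
  o <- order(pb$chrom, pb$start)
  idx <- idx[o]; pb <- pb[o, , drop = FALSE]
  mids <- (pb$start + pb$end) / 2
  meanM <- rowMeans(ps$M[idx, , drop = FALSE], na.rm = TRUE)
  if (any(meanM == 0))
    message(sum(meanM == 0),
            " probe(s) with mean M exactly 0 assigned direction +1")
  sgn <- ifelse(meanM >= 0, 1L, -1L)
  newrun <- c(TRUE, pb$chrom[-1] != pb$chrom[-nrow(pb)] |
                diff(mids) > gap_bp |
                sgn[-1] != sgn[-length(sgn)])
  run <- cumsum(newrun)
  out <- lapply(split(seq_along(idx), run), function(i) {
    j <- idx[i]
    data.frame(chrom = pb$chrom[i[1]],
               start = min(pb$start[i]),
               end = max(pb$end[i]),
               direction = sgn[i[1]],
               p_value = max(ps$p[j, , drop = FALSE], na.rm = TRUE),
               mean_A = mean(ps$A[j, , drop = FALSE], na.rm = TRUE),
               n_probes = length(i),
               probe_ids = paste(pb$probe_id[i], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Annotate regions with promoter gene and CpG content
#'
#' Assigns each region the promoter whose interval overlaps it (largest
#' overlap wins; ties break to the lexicographically smaller gene id, with
#' a message), counts CpG positions in [start, end), and derives the CpG
#' density in CpG per 100 bp. Regions with no promoter overlap get gene NA
#' and are flagged by message.
#'
#' @param regions Region data frame (chrom, start, end, ...).
#' @param annotation A \code{genome_annotation}.
#' @return The regions with columns gene, n_cpg, cpg_density added.
#' @export
annotate_regions <- function(regions, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (nrow(regions) == 0) {
    regions$gene <- character(0)
    regions$n_cpg <- integer(0)
    regions$cpg_density <- numeric(0)
    return(regions)
  }
  regions$gene <- NA_character_
  regions$n_cpg <- 0L
  regions$cpg_density <- 0
  pr <- annotation$promoters
  for (k in seq_len(nrow(regions))) {
    cand <- pr[pr$chrom == regions$chrom[k] &
                 pr$start < regions$end[k] & pr$end > regions$start[k], ,
               drop = FALSE]
    if (nrow(cand) > 0) {
      ov <- pmin(cand$end, regions$end[k]) - pmax(cand$start, regions$start[k])
      best <- which(ov == max(ov))
      if (length(best) > 1) {
        best <- best[order(cand$gene[best])][1]
        message("region ", k, " overlaps two promoters equally; ",
                "assigned ", cand$gene[best])
      }
      regions$gene[k] <- cand$gene[best]
    } else {
      message("region ", k, " (", regions$chrom[k], ":", regions$start[k],
              "-", regions$end[k], ") overlaps no promoter")
    }
  }
  regions$n_cpg <- count_cpgs(annotation, regions$chrom, regions$start,
                              regions$end)
  regions$cpg_density <- 100 * regions$n_cpg / (regions$end - regions$start)
  regions
}

#' Apply the intensity and CpG-density filters to candidate regions
#'
#' A region is kept iff its average intensity (mean A) exceeds
#' \code{min_mean_A} (strictly) and its CpG density is at least
#' \code{min_cpg_density} CpG/100 bp. Removed regions are logged with the
#' failing criterion.
#'
#' @param regions Annotated region data frame (needs mean_A, cpg_density).
#' @param min_mean_A Intensity floor on the log scale (default 9.5,
#'   exceeded strictly).
#' @param min_cpg_density CpG/100 bp floor (default 1, inclusive).
#' @return The retained regions; removed rows with reasons are attached as
#'   attribute \code{"removed"}.
#' @export
filter_regions <- function(regions, min_mean_A = 9.5, min_cpg_density = 1) {
  stopifnot(all(c("mean_A", "cpg_density") %in% names(regions)))
  ok_a <- regions$mean_A > min_mean_A
  ok_d <- regions$cpg_density >= min_cpg_density
  keep <- ok_a & ok_d
  if (any(!keep)) {
    reason <- ifelse(!ok_a & !ok_d, "mean_A,cpg_density",
                     ifelse(!ok_a, "mean_A", "cpg_density"))
    message(sum(!keep), " region(s) removed by filters (",
            paste(unique(reason[!keep]), collapse = "; "), ")")
    removed <- cbind(regions[!keep, , drop = FALSE],
                     failed = reason[!keep])
  } else removed <- regions[0, , drop = FALSE]
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Call DMRs from a smoothed MA profile set
#'
#' Convenience wrapper chaining \code{probe_z_scores},
#' \code{paired_intersection}, \code{cluster_probes_to_regions},
#' \code{annotate_regions} and \code{filter_regions} with the standard
#' thresholds (p < 1e-5, 600 bp joining gap, mean A > 9.5, >= 1 CpG/100 bp).
#'
#' @param ma An \code{ma_set} at stage \code{"smoothed"}.
#' @param annotation A \code{genome_annotation}.
#' @param threshold,gap_bp,min_mean_A,min_cpg_density Pipeline thresholds.
#' @return List with \code{dmrs} (final regions), \code{unfiltered},
#'   \code{pair_sizes}, and \code{significance}.
#' @export
call_dmrs <- function(ma, annotation, threshold = 1e-5, gap_bp = 600,
                      min_mean_A = 9.5, min_cpg_density = 1) {
  ps <- probe_z_scores(ma, threshold = threshold)
  pi <- paired_intersection(ps)
  regions <- cluster_probes_to_regions(ps, pi$retained, gap_bp = gap_bp)
  regions <- annotate_regions(regions, annotation)
  final <- filter_regions(regions, min_mean_A = min_mean_A,
                          min_cpg_density = min_cpg_density)
  list(dmrs = final, unfiltered = regions, pair_sizes = pi$pair_sizes,
       significance = ps)
}
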