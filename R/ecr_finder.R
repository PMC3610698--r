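#' Tile the genome with sliding windows and count genes
#'
#' Lays 2 Mb windows at a 50 kb stride along each chromosome and counts
#' the genes (and DE genes) whose gene-body midpoint falls in each
#' half-open window [start, end). A chromosome shorter than the window
#' gets a single truncated window, flagged.
#'
#' @param annotation A \code{genome_annotation}.
#' @param de_genes Character vector of DE gene ids (may be empty).
#' @param window_bp Window size (default 2 Mb).
#' @param step_bp Stride (default 50 kb).
#' @return Data frame of class \code{genome_windows}: chrom, start, end,
#'   truncated, n_genes, n_de_genes; attributes \code{window_bp},
#'   \code{step_bp}.
#' @export
make_windows <- function(annotation, de_genes = character(0),
                         window_bp = 2e6, step_bp = 5e4) {
  stopifnot(inherits(annotation, "genome_annotation"),
            window_bp >= step_bp)
  gb <- annotation$gene_bodies
  mid <- (gb$start + gb$end) / 2
  is_de <- gb$gene %in% de_genes
  rows <- lapply(names(annotation$chromosomes), function(cn) {
    L <- annotation$chromosomes[[cn]]
    if (L < window_bp) {
      df <- data.frame(chrom = cn, start = 0, end = L, truncated = TRUE)
    } else {
      starts <- seq(0, L - window_bp, by = step_bp)
      df <- data.frame(chrom = cn, start = starts, end = starts + window_bp,
                       truncated = FALSE)
    }
    i <- gb$chrom == cn
    df$n_genes <- vapply(seq_len(nrow(df)), function(w)
      sum(i & mid >= df$start[w] & mid < df$end[w]), integer(1))
    df$n_de_genes <- vapply(seq_len(nrow(df)), function(w)
      sum(i & is_de & mid >= df$start[w] & mid < df$end[w]), integer(1))
    df
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "window_bp") <- window_bp
  attr(out, "step_bp") <- step_bp
  class(out) <- c("genome_windows", "data.frame")
  out
}

#' One-proportion z-test for DE over-representation per window
#'
#' For each window with at least one gene, tests whether the window's DE
#' fraction exceeds the genome-wide DE fraction pi0:
#' z = (n_de/n - pi0) / sqrt(pi0 (1 - pi0) / n), with a one-sided
#' upper-tail normal p-value. A window is over-represented when
#' p < alpha. Windows with zero genes are flagged untestable (NA).
#'
#' @param windows A \code{genome_windows} data frame.
#' @param genome_de_fraction Reference proportion pi0 in (0, 1); defaults
#'   to total DE genes / total genes summed over non-overlapping gene
#'   counts is not well-defined from windows, so pass it explicitly or it
#'   is taken from attribute \code{"pi0"} if present.
#' @param alpha Significance level (default 0.05).
#' @return The windows with z_score, p_value, over_represented and
#'   testable columns added.
#' @export
window_overrep_test <- function(windows, genome_de_fraction, alpha = 0.05) {
  pi0 <- genome_de_fraction
  stopifnot(is.numeric(pi0), pi0 > 0, pi0 < 1)
  n <- windows$n_genes
  testable <- n >= 1
  z <- rep(NA_real_, nrow(windows))
  z[testable] <- (windows$n_de_genes[testable] / n[testable] - pi0) /
    sqrt(pi0 * (1 - pi0) / n[testable])
  p <- stats::pnorm(z, lower.tail = FALSE)
  windows$z_score <- z
  windows$p_value <- p
  windows$testable <- testable
  windows$over_represented <- !is.na(p) & p < alpha
  if (any(!testable))
    message(sum(!testable), " window(s) with no genes skipped as untestable")
  windows
}

#' Merge consecutive over-represented windows into ECR clusters
#'
#' Maximal runs of over-represented windows at consecutive strides (same
#' chromosome, starts one step apart) are merged; the cluster interval is
#' the union of its member windows and its member DE genes are the DE
#' genes whose gene-body midpoint falls inside the cluster.
#'
#' @param windows Output of \code{\link{window_overrep_test}}, sorted by
#'   (chrom, start).
#' @param annotation A \code{genome_annotation} (for gene membership).
#' @param de_genes Character vector of DE gene ids.
#' @return Data frame of clusters: chrom, start, end, span, n_windows,
#'   n_de_genes, de_genes (comma separated).
#' @export
merge_windows <- function(windows, annotation = NULL,
                          de_genes = character(0)) {
  step <- attr(windows, "step_bp")
  if (is.null(step)) step <- 5e4
  ov <- windows[windows$over_represented %in% TRUE, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), span = numeric(0),
                      n_windows = integer(0), n_de_genes = integer(0),
                      de_genes = character(0), stringsAsFactors = FALSE)
  if (nrow(ov) == 0) return(empty)
  ov <- ov[order(ov$chrom, ov$start), , drop = FALSE]
  newrun <- c(TRUE, ov$chrom[-1] != ov$chrom[-nrow(ov)] |
                (ov$start[-1] - ov$start[-nrow(ov)]) > step)
  run <- cumsum(newrun)
  out <- lapply(split(seq_len(nrow(ov)), run), function(i) {
    s <- min(ov$start[i]); e <- max(ov$end[i])
    genes <- character(0)
    if (!is.null(annotation) && length(de_genes)) {
      gb <- annotation$gene_bodies
      mid <- (gb$start + gb$end) / 2
      genes <- gb$gene[gb$chrom == ov$chrom[i[1]] & gb$gene %in% de_genes &
                         mid >= s & mid < e]
    }
    data.frame(chrom = ov$chrom[i[1]], start = s, end = e, span = e - s,
               n_windows = length(i), n_de_genes = length(genes),
               de_genes = paste(genes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Associate DMRs with ECR clusters by genomic distance
#'
#' A DMR is associated with a cluster when the gap between their
#' intervals is at most \code{max_distance_bp} (a DMR inside a cluster is
#' at distance 0). Many-to-many pairs are allowed.
#'
#' @param clusters,dmrs Region data frames (chrom, start, end).
#' @param max_distance_bp Association distance (default 2 Mb).
#' @return Data frame: cluster_idx, dmr_idx, distance_bp.
#' @export
associate_dmrs <- function(clusters, dmrs, max_distance_bp = 2e6) {
  empty <- data.frame(cluster_idx = integer(0), dmr_idx = integer(0),
                      distance_bp = numeric(0))
  if (nrow(clusters) == 0 || nrow(dmrs) == 0) return(empty)
  out <- empty
  for (i in seq_len(nrow(clusters))) {
    j <- which(dmrs$chrom == clusters$chrom[i])
    if (!length(j)) next
    gap <- pmax(0, pmax(dmrs$start[j] - clusters$end[i],
                        clusters$start[i] - dmrs$end[j]))
    keep <- gap <= max_distance_bp
    if (any(keep))
      out <- rbind(out, data.frame(cluster_idx = i, dmr_idx = j[keep],
                                   distance_bp = gap[keep]))
  }
  rownames(out) <- NULL
  out
}

#' Correlate DMRs with differentially expressed genes
#'
#' Direct pairs: the DMR's promoter gene is itself differentially
#' expressed. Distal pairs: the DMR interval lies within
#' \code{max_distance_bp} of a DE gene's body interval, excluding direct
#' pairs. Each table reports its unique DMR and gene counts.
#'
#' @param dmrs DMR data frame carrying a \code{gene} (promoter) column.
#' @param de_genes Character vector of selected DE gene ids.
#' @param annotation A \code{genome_annotation} (gene-body intervals).
#' @param max_distance_bp Distal association distance (default 2 Mb).
#' @return List with \code{direct} and \code{distal} pair tables and a
#'   \code{counts} list (n_direct_pairs, n_distal_pairs, n_distal_dmrs,
#'   n_distal_genes).
#' @export
correlate_dmr_expression <- function(dmrs, de_genes, annotation,
                                     max_distance_bp = 2e6) {
  stopifnot(inherits(annotation, "genome_annotation"))
  gb <- annotation$gene_bodies
  missing <- setdiff(de_genes, gb$gene)
  if (length(missing)) {
    warning("DE gene(s) not in annotation, excluded: ",
            paste(missing, collapse = ", "))
    de_genes <- setdiff(de_genes, missing)
  }
  direct <- data.frame(dmr_idx = integer(0), gene = character(0))
  distal <- data.frame(dmr_idx = integer(0), gene = character(0),
                       distance_bp = numeric(0))
  if (nrow(dmrs) > 0 && length(de_genes) > 0) {
    di <- which(!is.na(dmrs$gene) & dmrs$gene %in% de_genes)
    direct <- data.frame(dmr_idx = di, gene = dmrs$gene[di],
                         stringsAsFactors = FALSE)
    deb <- gb[gb$gene %in% de_genes, , drop = FALSE]
    for (i in seq_len(nrow(dmrs))) {
      j <- which(deb$chrom == dmrs$chrom[i])
      if (!length(j)) next
      gap <- pmax(0, pmax(deb$start[j] - dmrs$end[i],
                          dmrs$start[i] - deb$end[j]))
      keep <- gap <= max_distance_bp &
        !(i %in% di & deb$gene[j] == dmrs$gene[i])
      if (any(keep))
        distal <- rbind(distal,
                        data.frame(dmr_idx = i, gene = deb$gene[j][keep],
                                   distance_bp = gap[keep],
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(distal) <- NULL
  list(direct = direct, distal = distal,
       counts = list(n_direct_pairs = nrow(direct),
                     n_distal_pairs = nrow(distal),
                     n_distal_dmrs = length(unique(distal$dmr_idx)),
                     n_distal_genes = length(unique(distal$gene))))
}
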