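#' CpG density histogram of a DMR set
#'
#' Bins region CpG densities (CpG per 100 bp) into [k, k + bin_width)
#' bins from zero up to \code{max_bin}; densities at or above
#' \code{max_bin} are pooled into a final open bin. The counts always sum
#' to the number of regions.
#'
#' @param regions Region data frame carrying \code{cpg_density}, or a
#'   numeric vector of densities.
#' @param bin_width Bin width in CpG/100 bp.
#' @param max_bin Lower edge of the final open bin.
#' @return Named integer vector of bin counts.
#' @export
cpg_density_histogram <- function(regions, bin_width = 1, max_bin = 11) {
  d <- if (is.data.frame(regions)) regions$cpg_density else as.numeric(regions)
  edges <- seq(0, max_bin, by = bin_width)
  labs <- c(sprintf("[%g,%g)", edges[-length(edges)], edges[-1]),
            sprintf("[%g,Inf)", max_bin))
  counts <- integer(length(labs))
  names(counts) <- labs
  if (length(d) == 0) return(counts)
  bin <- pmin(floor(d / bin_width) + 1L, length(labs))
  tab <- table(factor(bin, levels = seq_along(labs)))
  counts[] <- as.integer(tab)
  counts
}

#' Scan sequences for a motif on both strands
#'
#' Matches an IUPAC consensus (exact, ambiguity codes expanded on the
#' motif side only: an N in a sequence never matches a non-N consensus
#' position) or a position-weight matrix at a log-odds score threshold,
#' on both strands. Offsets are reported 0-based on the forward
#' coordinate system (start of the matched window, for either strand).
#'
#' @param sequences A \code{Biostrings::DNAStringSet} or named character
#'   vector over \{A,C,G,T,N\}.
#' @param motif Either an IUPAC consensus string, or a list with
#'   \code{pwm} (4 x L matrix, rows A/C/G/T, columns summing to 1) and
#'   \code{threshold} (log2-odds score floor vs uniform background).
#' @return List with \code{hits} (named logical) and \code{offsets}
#'   (named list of 0-based forward-strand offsets).
#' @export
scan_motif <- function(sequences, motif) {
  if (is.character(sequences)) {
    bad <- grepl("[^ACGTN]", toupper(sequences))
    if (any(bad))
      stop("sequences contain characters other than A, C, G, T, N")
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  stopifnot(methods::is(sequences, "DNAStringSet"))
  if (any(grepl("[^ACGTN]", as.character(sequences))))
    stop("sequences contain characters other than A, C, G, T, N")
  n <- length(sequences)
  ids <- if (!is.null(names(sequences))) names(sequences)
         else as.character(seq_len(n))
  offsets <- stats::setNames(vector("list", n), ids)

  if (is.character(motif)) {
    check_iupac(motif)
    # fixed = pattern FALSE: consensus ambiguity codes expand; subject
    # ambiguities (N) stay literal and never match a non-N position
    fwd <- Biostrings::vmatchPattern(motif, sequences,
                                     fixed = c(pattern = FALSE, subject = TRUE))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    rev <- Biostrings::vmatchPattern(rc, sequences,
                                     fixed = c(pattern = FALSE, subject = TRUE))
    for (k in seq_len(n))
      offsets[[k]] <- sort(unique(c(BiocGenerics::start(fwd[[k]]),
                                    BiocGenerics::start(rev[[k]])))) - 1L
  } else if (is.list(motif) && !is.null(motif$pwm)) {
    pwm <- motif$pwm
    stopifnot(nrow(pwm) == 4, all(abs(colSums(pwm) - 1) < 1e-6))
    rownames(pwm) <- c("A", "C", "G", "T")
    lo <- log2((pwm + 1e-6) / 0.25)
    for (k in seq_len(n)) {
      s <- sequences[[k]]
      f <- Biostrings::matchPWM(lo, s, min.score = motif$threshold)
      r <- Biostrings::matchPWM(Biostrings::reverseComplement(lo), s,
                                min.score = motif$threshold)
      offsets[[k]] <- sort(unique(c(BiocGenerics::start(f),
                                    BiocGenerics::start(r)))) - 1L
    }
  } else stop("motif must be an IUPAC consensus string or list(pwm, threshold)")

  hits <- vapply(offsets, function(o) length(o) > 0, logical(1))
  list(hits = hits, offsets = offsets)
}

#' Compare motif incidence between two sequence sets
#'
#' Two-proportion z-test of the fraction of sequences with at least one
#' motif hit, with a Fisher exact fallback when any expected cell count is
#' below 5.
#'
#' @param set_a_flags,set_b_flags Logical hit flags for the two sets.
#' @param labels Character labels for the two sets.
#' @return Data frame of class \code{incidence_comparison}: one row per
#'   set (label, n_sequences, n_with_motif, incidence) with the shared
#'   \code{p_value}, \code{z} and \code{method} as attributes (also in
#'   columns).
#' @export
compare_incidence <- function(set_a_flags, set_b_flags,
                              labels = c("set_a", "set_b")) {
  n1 <- length(set_a_flags); n2 <- length(set_b_flags)
  if (n1 == 0 || n2 == 0)
    stop("both sequence sets must be non-empty")
  x1 <- sum(set_a_flags); x2 <- sum(set_b_flags)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  expected <- c(n1 * pp, n1 * (1 - pp), n2 * pp, n2 * (1 - pp))
  if (any(expected < 5)) {
    method <- "fisher"
    z <- NA_real_
    pv <- stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2,
                                    byrow = TRUE))$p.value
  } else {
    method <- "two-proportion z"
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (p1 - p2) / se
    pv <- 2 * stats::pnorm(-abs(z))
  }
  out <- data.frame(label = labels, n_sequences = c(n1, n2),
                    n_with_motif = c(x1, x2), incidence = c(p1, p2),
                    p_value = pv, z = z, method = method,
                    stringsAsFactors = FALSE)
  class(out) <- c("incidence_comparison", "data.frame")
  out
}

#' Overlapping pairs between two DMR sets
#'
#' Reports all pairs of regions from the two sets whose intervals overlap
#' by at least \code{min_overlap_bp}. Errors when the two sets share no
#' chromosome names (likely a naming-convention mismatch).
#'
#' @param set_a,set_b Region data frames (chrom, start, end).
#' @param min_overlap_bp Minimum overlap in bp.
#' @return Data frame with a_idx, b_idx, overlap_bp; the pair count is
#'   \code{nrow()} of the result.
#' @export
overlap_dmr_sets <- function(set_a, set_b, min_overlap_bp = 1) {
  empty <- data.frame(a_idx = integer(0), b_idx = integer(0),
                      overlap_bp = numeric(0))
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(empty)
  shared <- intersect(unique(set_a$chrom), unique(set_b$chrom))
  if (length(shared) == 0)
    stop("no shared chromosome names between sets; unshared: ",
         paste(union(set_a$chrom, set_b$chrom), collapse = ", "))
  ga <- regions_to_granges(set_a)
  gb <- regions_to_granges(set_b)
  hv <- GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap_bp)
  ai <- S4Vectors::queryHits(hv); bi <- S4Vectors::subjectHits(hv)
  ov <- pmin(set_a$end[ai], set_b$end[bi]) - pmax(set_a$start[ai], set_b$start[bi])
  data.frame(a_idx = ai, b_idx = bi, overlap_bp = ov)
}

# 0-based half-open data frame -> GRanges (1-based closed)
regions_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}
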