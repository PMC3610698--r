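#' Generate a synthetic promoter-tiling genome annotation
#'
#' Builds a desk-scale genome annotation emulating the geometry of a
#' NimbleGen-style CpG-island-plus-promoter tiling array: non-overlapping
#' promoters spanning 3,880 bp upstream to 970 bp downstream of each TSS,
#' tiled with 50-75-mer probes at ~100 bp median spacing, with per-promoter
#' CpG densities drawn from a user-supplied mixture of CpG/100 bp classes.
#'
#' The defaults give roughly a 35x linear reduction of the real platform:
#' 2 chromosomes x 10 Mb, 400 promoters, ~19,000 probes.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp (scalar or vector
#'   of length \code{n_chromosomes}).
#' @param n_promoters Total number of promoters to place (split as evenly as
#'   possible across chromosomes). May be 0.
#' @param cpg_density_mix Named numeric vector: names are CpG/100 bp density
#'   classes, values are mixture weights (normalized internally). Must cover
#'   at least part of the 0-10 range.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param upstream_bp,downstream_bp Promoter span around the TSS (defaults
#'   3,880 and 970 bp).
#' @param probe_spacing_bp Target spacing of adjacent probe midpoints.
#' @param probe_length_range Inclusive range of probe lengths (bp).
#' @param gene_length_range Range of gene-body lengths (bp), clipped to the
#'   chromosome.
#'
#' @return An object of class \code{genome_annotation}: a list with
#'   \code{chromosomes} (named lengths), \code{promoters},
#'   \code{gene_bodies}, \code{cpg} (chrom/pos, sorted), \code{probes}
#'   (probe_id, chrom, start, end, gc, gene) and \code{params}. All
#'   coordinates are 0-based half-open; strand affects only promoter and
#'   gene-body construction.
#' @export
generate_genome <- function(n_chromosomes = 2,
                            chrom_length_bp = 10e6,
                            n_promoters = 400,
                            cpg_density_mix = c(`1` = 0.4, `2` = 0.3,
                                                `3` = 0.15, `4` = 0.1,
                                                `8` = 0.05),
                            seed = 1,
                            upstream_bp = 3880,
                            downstream_bp = 970,
                            probe_spacing_bp = 100,
                            probe_length_range = c(50, 75),
                            gene_length_range = c(5e3, 5e4)) {
  stopifnot(n_chromosomes >= 1, n_promoters >= 0,
            length(cpg_density_mix) >= 1, all(cpg_density_mix >= 0),
            sum(cpg_density_mix) > 0)
  if (is.null(names(cpg_density_mix)))
    stop("cpg_density_mix must be named by CpG/100 bp density class")
  mix <- cpg_density_mix / sum(cpg_density_mix)
  chrom_len <- rep_len(as.numeric(chrom_length_bp), n_chromosomes)
  chroms <- stats::setNames(chrom_len, paste0("chr", seq_len(n_chromosomes)))
  span <- upstream_bp + downstream_bp

  set.seed(as.integer(seed))

  # split promoters across chromosomes as evenly as possible
  n_per_chrom <- diff(floor(seq(0, n_promoters, length.out = n_chromosomes + 1)))

  promoters <- list(); bodies <- list(); cpg <- list(); probes <- list()
  gid <- 0L; pid <- 0L
  for (ci in seq_len(n_chromosomes)) {
    cn <- names(chroms)[ci]; L <- chroms[[ci]]; n_c <- n_per_chrom[ci]
    if (n_c == 0) next
    if (n_c * span > L)
      stop(sprintf("cannot fit %d promoters of %d bp on a %g bp chromosome",
                   n_c, span, L))
    # random non-overlapping placement: partition the free space into gaps
    free <- L - n_c * span
    g <- stats::runif(n_c + 1)
    g <- g / sum(g) * free
    starts <- floor(cumsum(g[seq_len(n_c)]) + (seq_len(n_c) - 1) * span)
    strand <- sample(c("+", "-"), n_c, replace = TRUE)
    tss <- ifelse(strand == "+", starts + upstream_bp, starts + downstream_bp)
    genes <- sprintf("G%04d", gid + seq_len(n_c)); gid <- gid + n_c

    promoters[[cn]] <- data.frame(
      gene = genes, chrom = cn, tss = tss, strand = strand,
      start = starts, end = starts + span, stringsAsFactors = FALSE)

    glen <- round(stats::runif(n_c, gene_length_range[1], gene_length_range[2]))
    gb_start <- ifelse(strand == "+", tss, pmax(0, tss - glen))
    gb_end <- ifelse(strand == "+", pmin(L, tss + glen), tss)
    bodies[[cn]] <- data.frame(
      gene = genes, chrom = cn, start = gb_start, end = gb_end,
      strand = strand, stringsAsFactors = FALSE)

    # per-promoter CpG density class, realized as uniform CpG placement
    cls <- as.numeric(sample(names(mix), n_c, replace = TRUE, prob = mix))
    cpg_pos <- vector("list", n_c)
    probe_rows <- vector("list", n_c)
    for (k in seq_len(n_c)) {
      n_cpg <- round(cls[k] * span / 100)
      if (n_cpg > 0)
        cpg_pos[[k]] <- sort(sample.int(span - 1L, n_cpg)) + starts[k] - 1L
      # probe midpoints tile the promoter at the stated spacing
      mids <- seq(probe_spacing_bp / 2, span - probe_spacing_bp / 2,
                  by = probe_spacing_bp)
      plen <- sample(seq(probe_length_range[1], probe_length_range[2]),
                     length(mids), replace = TRUE)
      ps <- round(starts[k] + mids - plen / 2)
      gc <- pmin(0.8, pmax(0.2, 0.38 + 0.015 * cls[k] +
                             stats::rnorm(length(mids), 0, 0.05)))
      probe_rows[[k]] <- data.frame(
        chrom = cn, start = ps, end = ps + plen, gc = gc,
        gene = genes[k], stringsAsFactors = FALSE)
    }
    cp <- sort(unlist(cpg_pos))
    if (length(cp))
      cpg[[cn]] <- data.frame(chrom = cn, pos = cp, stringsAsFactors = FALSE)
    pr <- do.call(rbind, probe_rows)
    pr$probe_id <- sprintf("P%06d", pid + seq_len(nrow(pr)))
    pid <- pid + nrow(pr)
    probes[[cn]] <- pr[, c("probe_id", "chrom", "start", "end", "gc", "gene")]
  }

  empty_df <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df
  }
  ann <- structure(list(
    chromosomes = chroms,
    promoters = if (length(promoters)) do.call(rbind, c(promoters, make.row.names = FALSE))
                else empty_df(c("gene", "chrom", "tss", "strand", "start", "end")),
    gene_bodies = if (length(bodies)) do.call(rbind, c(bodies, make.row.names = FALSE))
                  else empty_df(c("gene", "chrom", "start", "end", "strand")),
    cpg = if (length(cpg)) do.call(rbind, c(cpg, make.row.names = FALSE))
          else data.frame(chrom = character(0), pos = numeric(0)),
    probes = if (length(probes)) do.call(rbind, c(probes, make.row.names = FALSE))
             else empty_df(c("probe_id", "chrom", "start", "end", "gc", "gene")),
    params = list(upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                  probe_spacing_bp = probe_spacing_bp,
                  probe_length_range = probe_length_range,
                  cpg_density_mix = mix, seed = as.integer(seed))
  ), class = "genome_annotation")
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(paste0("genome_annotation: %d chromosome(s), %d promoters, ",
                     "%d probes, %d CpGs\n"),
              length(x$chromosomes), nrow(x$promoters), nrow(x$probes),
              nrow(x$cpg)))
  invisible(x)
}

#' Count CpG positions falling in an interval
#'
#' @param annotation A \code{genome_annotation}.
#' @param chrom,start,end Interval (0-based half-open), vectorized.
#' @return Integer vector of CpG counts in \code{[start, end)}.
#' @export
count_cpgs <- function(annotation, chrom, start, end) {
  out <- integer(length(chrom))
  for (cn in unique(chrom)) {
    pos <- annotation$cpg$pos[annotation$cpg$chrom == cn]
    i <- which(chrom == cn)
    if (length(pos) == 0) { out[i] <- 0L; next }
    # pos sorted: count pos in [start, end)
    out[i] <- findInterval(end[i] - 1e-9, pos) - findInterval(start[i] - 1e-9, pos)
  }
  out
}
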