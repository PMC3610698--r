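#' Plant ground truth for a synthetic study
#'
#' Chooses the planted signal a synthetic run will carry: differential
#' methylation regions (DMRs) as runs of consecutive probes inside
#' promoters, differentially expressed (DE) genes with a fold-change
#' multiplier, chromosomal cluster intervals inside which DE status is
#' enriched, and promoter sequences carrying a planted motif occurrence.
#' Downstream recovery is always scored against this record, never against
#' generator internals.
#'
#' DMR intervals are drawn without replacement over promoters and accepted
#' only if their realized CpG density meets \code{dmr_min_cpg_density}, so
#' that planted regions are recoverable under the density filter the DMR
#' caller applies.
#'
#' @param annotation A \code{genome_annotation}.
#' @param n_dmrs Number of DMRs to plant.
#' @param dmr_probes Integer range: number of consecutive probes per DMR.
#' @param dmr_delta_m Absolute M-shift of planted DMRs (log2 scale); sign
#'   is drawn at random per region.
#' @param dmr_min_cpg_density Minimum realized CpG/100 bp for a planted DMR.
#' @param de_background_rate Probability that a gene outside any planted
#'   cluster is DE.
#' @param de_multiplier Fold-change multiplier (>= 1) of planted DE genes;
#'   up/down direction drawn at random per gene.
#' @param n_clusters Number of planted DE-gene cluster intervals.
#' @param cluster_length_bp Length of each planted cluster interval.
#' @param cluster_enrichment DE probability inside a cluster is
#'   \code{min(0.9, cluster_enrichment * de_background_rate)}.
#' @param motif_fraction Fraction of promoters carrying a planted motif.
#' @param motif_length_bp Length of the motif that will be planted (used to
#'   bound offsets).
#' @param seed Integer seed.
#'
#' @return An object of class \code{synthetic_truth}: list with
#'   \code{dmrs} (chrom, start, end, effect, gene, n_probes),
#'   \code{de_genes} (gene, direction, multiplier), \code{clusters}
#'   (chrom, start, end), \code{motif_sites} (named list: gene ->
#'   0-based offsets within the promoter sequence), and \code{seed}.
#' @export
plant_truth <- function(annotation,
                        n_dmrs = 20,
                        dmr_probes = c(6, 10),
                        dmr_delta_m = 1.2,
                        dmr_min_cpg_density = 1,
                        de_background_rate = 0.05,
                        de_multiplier = 2,
                        n_clusters = 1,
                        cluster_length_bp = 1e6,
                        cluster_enrichment = 10,
                        motif_fraction = 0.1,
                        motif_length_bp = 21,
                        seed = 1) {
  stopifnot(inherits(annotation, "genome_annotation"),
            n_dmrs >= 0, dmr_delta_m >= 0, de_multiplier >= 1)
  set.seed(as.integer(seed))
  pr <- annotation$promoters

  ## --- DMRs: runs of consecutive probes within one promoter -------------
  dmrs <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), effect = numeric(0),
                     gene = character(0), n_probes = integer(0))
  if (n_dmrs > 0) {
    if (nrow(pr) == 0) stop("cannot plant DMRs: annotation has no promoters")
    cand <- sample(pr$gene)
    picked <- list()
    for (g in cand) {
      if (length(picked) >= n_dmrs) break
      pp <- annotation$probes[annotation$probes$gene == g, , drop = FALSE]
      ks <- seq(dmr_probes[1], dmr_probes[2])
      k <- ks[sample.int(length(ks), 1)]
      if (nrow(pp) < k) next
      i0 <- sample.int(nrow(pp) - k + 1L, 1)
      run <- pp[i0:(i0 + k - 1L), ]
      s <- min(run$start); e <- max(run$end)
      dens <- 100 * count_cpgs(annotation, run$chrom[1], s, e) / (e - s)
      if (dens < dmr_min_cpg_density) next
      picked[[length(picked) + 1L]] <- data.frame(
        chrom = run$chrom[1], start = s, end = e,
        effect = sample(c(-1, 1), 1) * dmr_delta_m,
        gene = g, n_probes = k, stringsAsFactors = FALSE)
    }
    if (length(picked) < n_dmrs)
      warning(sprintf("only %d of %d requested DMRs could be planted",
                      length(picked), n_dmrs))
    if (length(picked)) dmrs <- do.call(rbind, picked)
  }

  ## --- planted cluster intervals ----------------------------------------
  clusters <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0))
  if (n_clusters > 0) {
    cn <- sample(names(annotation$chromosomes), n_clusters,
                 replace = n_clusters > length(annotation$chromosomes))
    cs <- vapply(cn, function(ch)
      floor(stats::runif(1, 0, annotation$chromosomes[[ch]] - cluster_length_bp)),
      numeric(1))
    clusters <- data.frame(chrom = cn, start = cs, end = cs + cluster_length_bp,
                           stringsAsFactors = FALSE, row.names = NULL)
  }

  ## --- DE genes: background rate, enriched inside clusters --------------
  de_genes <- data.frame(gene = character(0), direction = integer(0),
                         multiplier = numeric(0))
  if (nrow(pr) > 0 && (de_background_rate > 0 || nrow(clusters) > 0)) {
    gb <- annotation$gene_bodies
    mid <- (gb$start + gb$end) / 2
    in_cluster <- rep(FALSE, nrow(gb))
    for (j in seq_len(nrow(clusters)))
      in_cluster <- in_cluster | (gb$chrom == clusters$chrom[j] &
                                    mid >= clusters$start[j] &
                                    mid < clusters$end[j])
    p_de <- ifelse(in_cluster,
                   pmin(0.9, cluster_enrichment * de_background_rate),
                   de_background_rate)
    is_de <- stats::runif(nrow(gb)) < p_de
    if (any(is_de))
      de_genes <- data.frame(
        gene = gb$gene[is_de],
        direction = sample(c(-1L, 1L), sum(is_de), replace = TRUE),
        multiplier = de_multiplier, stringsAsFactors = FALSE)
  }

  ## --- motif sites -------------------------------------------------------
  motif_sites <- list()
  if (motif_fraction > 0 && nrow(pr) > 0) {
    span <- annotation$params$upstream_bp + annotation$params$downstream_bp
    n_m <- round(motif_fraction * nrow(pr))
    carriers <- sample(pr$gene, n_m)
    motif_sites <- stats::setNames(
      lapply(carriers, function(g)
        sample.int(span - motif_length_bp, 1) - 1L),
      carriers)
  }

  structure(list(dmrs = dmrs, de_genes = de_genes, clusters = clusters,
                 motif_sites = motif_sites, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Empty planted truth (null study: no DMRs, no DE genes, no motifs)
#' @param seed Integer seed recorded in the truth object.
#' @return A \code{synthetic_truth} with nothing planted.
#' @export
null_truth <- function(seed = 1) {
  structure(list(
    dmrs = data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), effect = numeric(0),
                      gene = character(0), n_probes = integer(0)),
    de_genes = data.frame(gene = character(0), direction = integer(0),
                          multiplier = numeric(0)),
    clusters = data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0)),
    motif_sites = list(), seed = as.integer(seed)), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d DMRs, %d DE genes, %d clusters, %d motif sites (seed %d)\n",
              nrow(x$dmrs), nrow(x$de_genes), nrow(x$clusters),
              length(x$motif_sites), x$seed))
  invisible(x)
}

#' Write/read the planted truth as a JSON sidecar
#'
#' @param truth A \code{synthetic_truth}.
#' @param path File path.
#' @return \code{read_truth} returns the \code{synthetic_truth}.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$motif_sites <- lapply(x$motif_sites, as.integer)
  for (f in c("dmrs", "de_genes", "clusters"))
    x[[f]] <- as.data.frame(x[[f]], stringsAsFactors = FALSE)
  structure(x, class = "synthetic_truth")
}
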