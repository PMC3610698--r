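#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults: 600 bp smoothing
#' window and 3-probe minimum, probe significance p < 1e-5, region joining
#' gap 600 bp, mean intensity > 9.5, CpG density >= 1/100 bp, 2 Mb ECR
#' window at 50 kb stride with alpha 0.05, and the DE gates p < 0.05,
#' fold > 1.2, un-logged mean difference > 10. The \code{simulate} block
#' holds the synthetic-study conditions. Unknown keys passed to
#' \code{\link{run_pipeline}} are rejected before any compute.
#'
#' @return Nested named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1,
    output_dir = NULL,
    simulate = list(
      n_chromosomes = 2, chrom_length_bp = 10e6, n_promoters = 400,
      n_dmrs = 20, dmr_delta_m = 1.2, n_clusters = 1,
      cluster_length_bp = 1e6, cluster_enrichment = 10,
      de_background_rate = 0.05, de_multiplier = 2,
      motif_fraction = 0.1,
      noise_sd = 0.3, dye_bias_amplitude = 1, n_pairs = 3,
      n_per_group = 3, batch_effect_sd = 0.3, expr_noise_sd = 0.2,
      motif_background_rate = 0.15
    ),
    normalize = list(gc_groups = 10, loess_span = 0.4, window_bp = 600,
                     min_probes = 3, pool_arrays = FALSE),
    dmr = list(p_threshold = 1e-5, gap_bp = 600, min_mean_A = 9.5,
               min_cpg_density = 1),
    features = list(motif_consensus = default_motif(), hist_max_bin = 11),
    de = list(p_max = 0.05, fold_min = 1.2, mean_diff_min = 10),
    ecr = list(window_bp = 2e6, step_bp = 5e4, alpha = 0.05,
               assoc_distance_bp = 2e6)
  )
}

# strict recursive key validation against the default tree
validate_config <- function(config, defaults = default_config(),
                            path = "config") {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(config[[k]]))
        stop(path, "$", k, " must be a list")
      validate_config(config[[k]], defaults[[k]], paste0(path, "$", k))
    }
  }
  invisible(TRUE)
}

# merge user config over defaults (after validation)
merge_config <- function(config, defaults = default_config()) {
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && is.list(config[[k]]))
      defaults[[k]] <- merge_config(config[[k]], defaults[[k]])
    else defaults[[k]] <- config[[k]]
  }
  defaults
}

# named substream seeds derived from the root seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offs <- c(genome = 101L, truth = 211L, hyb = 307L, expr = 401L,
            seqs = 503L, null = 601L)
  (as.integer(seed) * 1000L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> normalize -> DMR calling -> genomic features
#' -> DE selection -> ECR detection -> DMR/expression correlation, writes
#' every intermediate artifact when an output directory is configured,
#' and returns a run report with per-stage counts mirroring the printed
#' reporting style of the underlying study design (pairwise site counts,
#' filter survivors, up/down DE counts, windows flagged, clusters,
#' direct/distal pairs) plus a config echo. Deterministic for a fixed
#' seed: re-runs reproduce byte-identical outputs.
#'
#' @param config Partial configuration (see \code{\link{default_config}});
#'   may also be a path to a YAML file. Unknown keys are rejected.
#' @return List of class \code{pipeline_report} with the run's objects
#'   (annotation, truth, dmrs, de, clusters, correlations, ...) and a
#'   \code{counts} list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  cfg <- merge_config(config)
  sim <- cfg$simulate

  ann <- generate_genome(n_chromosomes = sim$n_chromosomes,
                         chrom_length_bp = sim$chrom_length_bp,
                         n_promoters = sim$n_promoters,
                         seed = stage_seed(cfg$seed, "genome"))
  truth <- plant_truth(ann, n_dmrs = sim$n_dmrs,
                       dmr_delta_m = sim$dmr_delta_m,
                       de_background_rate = sim$de_background_rate,
                       de_multiplier = sim$de_multiplier,
                       n_clusters = sim$n_clusters,
                       cluster_length_bp = sim$cluster_length_bp,
                       cluster_enrichment = sim$cluster_enrichment,
                       motif_fraction = sim$motif_fraction,
                       motif_length_bp = nchar(cfg$features$motif_consensus),
                       seed = stage_seed(cfg$seed, "truth"))
  hyb <- simulate_hybridizations(ann, truth, noise_sd = sim$noise_sd,
                                 dye_bias_amplitude = sim$dye_bias_amplitude,
                                 n_pairs = sim$n_pairs,
                                 seed = stage_seed(cfg$seed, "hyb"))
  expr <- simulate_expression(ann, truth, n_per_group = sim$n_per_group,
                              batch_effect_sd = sim$batch_effect_sd,
                              noise_sd = sim$expr_noise_sd,
                              seed = stage_seed(cfg$seed, "expr"))
  seqs <- simulate_promoter_sequences(ann, truth,
                                      motif_consensus = cfg$features$motif_consensus,
                                      background_rate = sim$motif_background_rate,
                                      seed = stage_seed(cfg$seed, "seqs"))

  ## normalization
  nm <- cfg$normalize
  ma <- ma_from_hyb(hyb)
  ma <- gc_group_loess(ma, n_groups = nm$gc_groups, span = nm$loess_span)
  ma <- aquantile_across_arrays(ma)
  ma <- window_median_smooth(ma, window_bp = nm$window_bp,
                             min_probes = nm$min_probes,
                             pool_arrays = nm$pool_arrays)

  ## DMR calling
  dm <- cfg$dmr
  dmr_run <- call_dmrs(ma, ann, threshold = dm$p_threshold,
                       gap_bp = dm$gap_bp, min_mean_A = dm$min_mean_A,
                       min_cpg_density = dm$min_cpg_density)
  dmrs <- dmr_run$dmrs

  ## genomic features
  hist_counts <- cpg_density_histogram(dmrs, max_bin = cfg$features$hist_max_bin)
  dmr_genes <- unique(stats::na.omit(dmrs$gene))
  feat <- NULL
  if (length(dmr_genes) >= 1) {
    set.seed(stage_seed(cfg$seed, "null"))
    bg_genes <- sample(setdiff(names(seqs), dmr_genes),
                       min(length(dmr_genes),
                           length(setdiff(names(seqs), dmr_genes))))
    scan_dmr <- scan_motif(seqs[dmr_genes], cfg$features$motif_consensus)
    scan_bg <- scan_motif(seqs[bg_genes], cfg$features$motif_consensus)
    feat <- compare_incidence(scan_dmr$hits, scan_bg$hits,
                              labels = c("dmr", "random_promoters"))
  }

  ## DE selection
  de <- select_de_genes(expr, p_max = cfg$de$p_max,
                        fold_min = cfg$de$fold_min,
                        diff_min = cfg$de$mean_diff_min)
  de_ids <- de$gene[de$selected]

  ## ECR detection
  ec <- cfg$ecr
  wins <- make_windows(ann, de_ids, window_bp = ec$window_bp,
                       step_bp = ec$step_bp)
  pi0 <- max(length(de_ids) / nrow(ann$gene_bodies), 1e-6)
  wins <- window_overrep_test(wins, genome_de_fraction = pi0,
                              alpha = ec$alpha)
  clusters <- merge_windows(wins, ann, de_ids)
  assoc <- associate_dmrs(clusters, dmrs,
                          max_distance_bp = ec$assoc_distance_bp)
  corr <- correlate_dmr_expression(dmrs, de_ids, ann,
                                   max_distance_bp = ec$assoc_distance_bp)

  counts <- list(
    n_probes = nrow(ann$probes),
    n_probes_valid = sum(ma$valid),
    pair_sizes = as.list(dmr_run$pair_sizes),
    n_regions_unfiltered = nrow(dmr_run$unfiltered),
    n_dmrs = nrow(dmrs),
    n_de_selected = unname(attr(de, "counts")["n_selected"]),
    n_de_up = unname(attr(de, "counts")["n_up"]),
    n_de_down = unname(attr(de, "counts")["n_down"]),
    n_windows_testable = sum(wins$testable),
    n_windows_flagged = sum(wins$over_represented),
    n_clusters = nrow(clusters),
    n_clusters_with_dmr = length(unique(assoc$cluster_idx)),
    n_direct_pairs = corr$counts$n_direct_pairs,
    n_distal_pairs = corr$counts$n_distal_pairs,
    n_distal_dmrs = corr$counts$n_distal_dmrs,
    n_distal_genes = corr$counts$n_distal_genes
  )

  report <- structure(list(
    config = cfg, annotation = ann, truth = truth, ma = ma,
    dmr_run = dmr_run, dmrs = dmrs, cpg_histogram = hist_counts,
    motif_comparison = feat, de = de, de_genes = de_ids,
    windows = wins, clusters = clusters, cluster_dmrs = assoc,
    correlations = corr, sequences = seqs, expression = expr,
    counts = counts), class = "pipeline_report")

  if (!is.null(cfg$output_dir)) write_pipeline_outputs(report, hyb)
  report
}

# write every intermediate artifact as plain text under config$output_dir
write_pipeline_outputs <- function(report, hyb) {
  dir <- report$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotation(report$annotation, file.path(dir, "annotation"))
  write_truth(report$truth, file.path(dir, "truth.json"))
  write_pair_table(hyb, file.path(dir, "hybridizations.tsv"))
  write_bed(report$truth$dmrs, file.path(dir, "planted_dmrs.bed"))
  write_stage_tsv(report$dmrs, file.path(dir, "dmrs.tsv"), "call_dmrs",
                  report$config$dmr)
  write_bed(report$dmrs, file.path(dir, "dmrs.bed"))
  write_stage_tsv(data.frame(bin = names(report$cpg_histogram),
                             count = as.integer(report$cpg_histogram)),
                  file.path(dir, "cpg_histogram.tsv"), "cpg_density_histogram")
  if (!is.null(report$motif_comparison))
    write_stage_tsv(as.data.frame(report$motif_comparison),
                    file.path(dir, "motif_incidence.tsv"), "compare_incidence")
  write_stage_tsv(report$de, file.path(dir, "de_genes.tsv"),
                  "select_de_genes", report$config$de)
  write_stage_tsv(report$windows, file.path(dir, "ecr_windows.tsv"),
                  "window_overrep_test", report$config$ecr)
  write_stage_tsv(report$clusters, file.path(dir, "ecr_clusters.tsv"),
                  "merge_windows")
  write_bed(report$clusters, file.path(dir, "ecr_clusters.bed"))
  write_stage_tsv(report$cluster_dmrs, file.path(dir, "cluster_dmrs.tsv"),
                  "associate_dmrs")
  write_stage_tsv(report$correlations$direct,
                  file.path(dir, "direct_pairs.tsv"), "correlate_dmr_expression")
  write_stage_tsv(report$correlations$distal,
                  file.path(dir, "distal_pairs.tsv"), "correlate_dmr_expression")
  Biostrings::writeXStringSet(report$sequences,
                              file.path(dir, "promoter_sequences.fasta"))
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  c <- x$counts
  cat("pipeline_report\n")
  cat(sprintf("  probes: %d (%d valid after smoothing)\n",
              c$n_probes, c$n_probes_valid))
  cat(sprintf("  pairwise significant sites: %s\n",
              paste(sprintf("%s=%d", names(c$pair_sizes),
                            unlist(c$pair_sizes)), collapse = ", ")))
  cat(sprintf("  regions: %d unfiltered -> %d final DMRs\n",
              c$n_regions_unfiltered, c$n_dmrs))
  cat(sprintf("  DE genes: %d selected (%d up, %d down)\n",
              c$n_de_selected, c$n_de_up, c$n_de_down))
  cat(sprintf("  ECR: %d/%d windows flagged -> %d clusters (%d with a DMR)\n",
              c$n_windows_flagged, c$n_windows_testable, c$n_clusters,
              c$n_clusters_with_dmr))
  cat(sprintf("  DMR-expression: %d direct pairs; %d distal pairs (%d DMRs, %d genes)\n",
              c$n_direct_pairs, c$n_distal_pairs, c$n_distal_dmrs,
              c$n_distal_genes))
  invisible(x)
}

#' Summary figures for a pipeline run
#'
#' Writes (1) a per-chromosome track plot of DMRs, DE genes and ECR
#' clusters and (2) the CpG-density histogram, as PDF files. Empty inputs
#' yield empty-axes figures, not failures. The plotted coordinates are
#' returned so they can be checked programmatically.
#'
#' @param report A \code{pipeline_report}.
#' @param dir Output directory for the figure files.
#' @return List with the two ggplot objects (\code{tracks},
#'   \code{histogram}) and the file paths, invisibly.
#' @export
plot_summaries <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- report$annotation
  gb <- ann$gene_bodies
  de_mid <- (gb$start + gb$end) / 2
  layers <- rbind(
    if (nrow(report$dmrs)) data.frame(chrom = report$dmrs$chrom,
                                      pos = (report$dmrs$start + report$dmrs$end) / 2,
                                      xmin = report$dmrs$start, xmax = report$dmrs$end,
                                      track = "DMR"),
    if (length(report$de_genes)) {
      i <- gb$gene %in% report$de_genes
      data.frame(chrom = gb$chrom[i], pos = de_mid[i],
                 xmin = de_mid[i], xmax = de_mid[i], track = "DE gene")
    },
    if (nrow(report$clusters)) data.frame(chrom = report$clusters$chrom,
                                          pos = (report$clusters$start + report$clusters$end) / 2,
                                          xmin = report$clusters$start,
                                          xmax = report$clusters$end,
                                          track = "ECR cluster"))
  p_tracks <- ggplot2::ggplot() +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "DMRs, DE genes and ECR clusters") +
    ggplot2::theme_minimal()
  if (!is.null(layers) && nrow(layers)) {
    p_tracks <- p_tracks +
      ggplot2::geom_segment(data = layers,
                            ggplot2::aes(x = xmin, xend = xmax,
                                         y = track, yend = track,
                                         colour = track),
                            linewidth = 3, show.legend = FALSE)
  }
  hist_df <- data.frame(bin = factor(names(report$cpg_histogram),
                                     levels = names(report$cpg_histogram)),
                        count = as.integer(report$cpg_histogram))
  p_hist <- ggplot2::ggplot(hist_df, ggplot2::aes(x = bin, y = count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "CpG density (CpG/100 bp)", y = "number of DMRs",
                  title = "DMR CpG density") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  f1 <- file.path(dir, "tracks.pdf")
  f2 <- file.path(dir, "cpg_histogram.pdf")
  grDevices::pdf(f1, width = 8, height = 5); print(p_tracks); grDevices::dev.off()
  grDevices::pdf(f2, width = 6, height = 4); print(p_hist); grDevices::dev.off()
  invisible(list(tracks = p_tracks, histogram = p_hist,
                 files = c(f1, f2), track_data = layers))
}
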