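#!/usr/bin/env Rscript
# Step 6: epigenetic control region (ECR) detection and DMR-expression
# correlation.
#
# 2 Mb windows at a 50 kb stride over gene-body midpoints; one-sided
# one-proportion z-test of each window's DE fraction against the
# genome-wide fraction (p < 0.05); consecutive flagged windows merged
# into clusters; DMRs associated with clusters within 2 Mb; direct
# (promoter DMR on a DE gene) and distal (DMR within 2 Mb of a DE gene)
# pair tables.

suppressMessages(library(medipdmr))

chroms <- read_stage_tsv("results/data/annotation/chromosomes.tsv")
ann <- structure(list(
  chromosomes = setNames(chroms$length, chroms$chrom),
  promoters = read_stage_tsv("results/data/annotation/promoters.tsv"),
  gene_bodies = read_stage_tsv("results/data/annotation/gene_bodies.tsv"),
  cpg = read_stage_tsv("results/data/annotation/cpg_positions.tsv"),
  probes = read_stage_tsv("results/data/annotation/probes.tsv"),
  params = list(upstream_bp = 3880, downstream_bp = 970)),
  class = "genome_annotation")
de <- read_stage_tsv("results/de_genes.tsv")
de_ids <- de$gene[de$selected]
dmrs <- read_stage_tsv("results/dmrs.tsv")

w <- make_windows(ann, de_ids, window_bp = 2e6, step_bp = 5e4)
pi0 <- length(de_ids) / nrow(ann$gene_bodies)
w <- window_overrep_test(w, genome_de_fraction = pi0, alpha = 0.05)
cat(sprintf("%d of %d testable windows over-represented (pi0 = %.3f)\n",
            sum(w$over_represented), sum(w$testable), pi0))

cl <- merge_windows(w, ann, de_ids)
cat(nrow(cl), "ECR clusters; spans (Mb):",
    paste(round(cl$span / 1e6, 2), collapse = ", "), "\n")

assoc <- associate_dmrs(cl, dmrs, max_distance_bp = 2e6)
cat(length(unique(assoc$cluster_idx)), "clusters have a DMR within 2 Mb\n")

corr <- correlate_dmr_expression(dmrs, de_ids, ann, max_distance_bp = 2e6)
cat(sprintf("Direct promoter-DMR/DE pairs: %d; distal: %d pairs (%d DMRs, %d genes)\n",
            corr$counts$n_direct_pairs, corr$counts$n_distal_pairs,
            corr$counts$n_distal_dmrs, corr$counts$n_distal_genes))

truth <- read_truth("results/data/truth.json")
cov <- interval_coverage(cl, truth$clusters)
cat(sprintf("Planted cluster interval coverage by ECRs: %.2f\n", cov))

write_stage_tsv(w, "results/ecr_windows.tsv", "window_overrep_test",
                list(window_bp = 2e6, step_bp = 5e4, alpha = 0.05))
write_stage_tsv(cl, "results/ecr_clusters.tsv", "merge_windows")
write_bed(cl, "results/ecr_clusters.bed")
write_stage_tsv(assoc, "results/cluster_dmrs.tsv", "associate_dmrs")
write_stage_tsv(corr$direct, "results/direct_pairs.tsv",
                "correlate_dmr_expression")
write_stage_tsv(corr$distal, "results/distal_pairs.tsv",
                "correlate_dmr_expression")
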