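#!/usr/bin/env Rscript
# Step 3: DMR calling.
#
# Probe Z-scores against the empirical normal per hybridization
# (p < 1e-5), intersection across all pairs of comparative
# hybridizations, clustering of retained probes (600 bp joining gap,
# shared mean-M sign), promoter/CpG annotation, and the intensity
# (mean A > 9.5) and CpG density (>= 1 CpG/100 bp) filters. Recovery is
# scored against the planted truth.

suppressMessages(library(medipdmr))

probes <- read_stage_tsv("results/data/annotation/probes.tsv")
sm <- read_stage_tsv("results/smoothed_ma.tsv")
stopifnot(identical(probes$probe_id, sm$probe_id))
Mh <- as.matrix(sm[grep("^M_", names(sm))])
Ah <- as.matrix(sm[grep("^A_", names(sm))])
ma <- ma_set(probes, Mh, Ah, stage = "smoothed", valid = sm$valid)

# annotation reconstructed from step 1's files
chroms <- read_stage_tsv("results/data/annotation/chromosomes.tsv")
ann <- structure(list(
  chromosomes = setNames(chroms$length, chroms$chrom),
  promoters = read_stage_tsv("results/data/annotation/promoters.tsv"),
  gene_bodies = read_stage_tsv("results/data/annotation/gene_bodies.tsv"),
  cpg = read_stage_tsv("results/data/annotation/cpg_positions.tsv"),
  probes = probes, params = list(upstream_bp = 3880, downstream_bp = 970)),
  class = "genome_annotation")

res <- call_dmrs(ma, ann, threshold = 1e-5, gap_bp = 600,
                 min_mean_A = 9.5, min_cpg_density = 1)
cat("Pairwise significant sites:",
    paste(sprintf("%s=%d", names(res$pair_sizes), res$pair_sizes),
          collapse = ", "), "\n")
cat(nrow(res$unfiltered), "candidate regions ->", nrow(res$dmrs),
    "final DMRs after filters\n")

truth <- read_truth("results/data/truth.json")
rec <- score_region_recovery(res$dmrs, truth$dmrs, min_reciprocal = 0.5)
cat(sprintf("Recovery vs planted truth: sensitivity %.2f, precision %.2f\n",
            rec$sensitivity, rec$precision))

write_stage_tsv(res$dmrs, "results/dmrs.tsv", "call_dmrs",
                list(p = 1e-5, gap_bp = 600, min_mean_A = 9.5,
                     min_cpg_density = 1))
write_bed(res$dmrs, "results/dmrs.bed")
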