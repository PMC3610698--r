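#!/usr/bin/env Rscript
# Step 5: differential expression selection.
#
# Per-gene additive two-factor model (treatment + batch) on log2 signals;
# selection by the three-criterion rule: treatment p < 0.05, fold change
# > 1.2, and un-logged mean difference > 10. Recovery is checked against
# the planted DE genes.

suppressMessages(library(medipdmr))

edf <- read_stage_tsv("results/data/expression.tsv")
samples <- read_stage_tsv("results/data/samples.tsv")
signals <- as.matrix(edf[, -1])
rownames(signals) <- edf$gene
expr <- list(signals = signals, samples = samples)

de <- select_de_genes(expr, p_max = 0.05, fold_min = 1.2, diff_min = 10)
cnt <- attr(de, "counts")
write_stage_tsv(de, "results/de_genes.tsv", "select_de_genes",
                list(p_max = 0.05, fold_min = 1.2, diff_min = 10))

truth <- read_truth("results/data/truth.json")
sel <- de$gene[de$selected]
cat(sprintf("Planted DE genes recovered: %d of %d\n",
            sum(truth$de_genes$gene %in% sel), nrow(truth$de_genes)))
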