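#!/usr/bin/env Rscript
# Step 2: three-stage normalization of the comparative hybridizations.
#
# Raw two-channel log2 signals -> MA values -> GC-grouped within-array
# loess (deciles of probe GC, span 0.4) -> A-quantile across arrays ->
# per-array 600 bp windowed median smoothing (minimum 3 probe positions,
# otherwise no value is assigned).

suppressMessages(library(medipdmr))

hyb <- read_pair_table("results/data/hybridizations.tsv")
ma <- ma_from_hyb(hyb)
ma <- gc_group_loess(ma, n_groups = 10, span = 0.4)
ma <- aquantile_across_arrays(ma)
ma <- window_median_smooth(ma, window_bp = 600, min_probes = 3)
print(ma)

df <- ma$probes["probe_id"]
df$valid <- ma$valid
for (h in seq_len(ncol(ma$M))) {
  df[[paste0("M_", h)]] <- ma$M[, h]
  df[[paste0("A_", h)]] <- ma$A[, h]
}
dir.create("results", showWarnings = FALSE)
write_stage_tsv(df, "results/smoothed_ma.tsv", "window_median_smooth",
                list(window_bp = 600, min_probes = 3, pool_arrays = FALSE))
cat(sprintf("%d of %d probes valid after smoothing\n", sum(ma$valid),
            nrow(df)))
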