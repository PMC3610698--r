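#!/usr/bin/env Rscript
# Step 7: one-command orchestrated run and summary figures.
#
# Re-runs the whole pipeline through run_pipeline() (same defaults and
# root seed as steps 1-6), prints the per-stage report, and writes the
# chromosome track plot (DMRs, DE genes, ECR clusters) and the
# CpG-density histogram under results/figures/.

suppressMessages(library(medipdmr))

report <- run_pipeline(list(seed = 1))
print(report)
figs <- plot_summaries(report, "results/figures")
cat("Figures written:", paste(figs$files, collapse = ", "), "\n")
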