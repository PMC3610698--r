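#!/usr/bin/env Rscript
# Step 1: generate the synthetic study.
#
# Desk-scale emulation of a promoter tiling-array methylation study:
# 2 chromosomes x 10 Mb, 400 promoters tiled with ~19,200 probes (50-75-mer,
# ~100 bp spacing, 3,880 bp upstream / 970 bp downstream of each TSS), with
# 20 planted DMRs, background + clustered DE genes, and planted motif
# occurrences. Everything downstream reads only these files.

suppressMessages(library(medipdmr))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- generate_genome(seed = seed)
truth <- plant_truth(ann, seed = seed)
hyb <- simulate_hybridizations(ann, truth, noise_sd = 0.3,
                               dye_bias_amplitude = 1, seed = seed)
expr <- simulate_expression(ann, truth, seed = seed)
seqs <- simulate_promoter_sequences(ann, truth, background_rate = 0.15,
                                    seed = seed)

write_annotation(ann, file.path(out, "annotation"))
write_truth(truth, file.path(out, "truth.json"))
write_pair_table(hyb, file.path(out, "hybridizations.tsv"))
edf <- data.frame(gene = rownames(expr$signals), expr$signals,
                  check.names = FALSE)
write_stage_tsv(edf, file.path(out, "expression.tsv"), "simulate_expression")
write_stage_tsv(expr$samples, file.path(out, "samples.tsv"),
                "simulate_expression")
Biostrings::writeXStringSet(seqs, file.path(out, "promoter_sequences.fasta"))
write_bed(truth$dmrs, file.path(out, "planted_dmrs.bed"))

print(ann)
print(truth)
cat("Planted DMR |delta-M| =", unique(abs(truth$dmrs$effect)),
    "(4 x noise_sd); planted DE multiplier =",
    unique(truth$de_genes$multiplier), "\n")
cat("Wrote synthetic study to", out, "\n")
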