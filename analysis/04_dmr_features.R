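#!/usr/bin/env Rscript
# Step 4: genomic features of the called DMR set.
#
# (1) CpG-density histogram (CpG/100 bp bins; DMRs are expected to sit in
# low-density "CpG desert" bins); (2) motif incidence in DMR promoter
# sequences vs a size-matched random promoter background, with a
# two-proportion test; (3) overlap with an independent (here: disjoint
# synthetic) DMR set, mirroring a cross-tissue comparison.

suppressMessages(library(medipdmr))

dmrs <- read_stage_tsv("results/dmrs.tsv")
seqs <- Biostrings::readDNAStringSet("results/data/promoter_sequences.fasta")

h <- cpg_density_histogram(dmrs, bin_width = 1, max_bin = 11)
write_stage_tsv(data.frame(bin = names(h), count = as.integer(h)),
                "results/cpg_histogram.tsv", "cpg_density_histogram")
cat("CpG density histogram (CpG/100 bp):\n")
print(h[h > 0])

dmr_genes <- unique(na.omit(dmrs$gene))
set.seed(2)
bg <- sample(setdiff(names(seqs), dmr_genes), length(dmr_genes))
sc_d <- scan_motif(seqs[dmr_genes], default_motif())
sc_b <- scan_motif(seqs[bg], default_motif())
cmp <- compare_incidence(sc_d$hits, sc_b$hits,
                         labels = c("dmr_promoters", "random_promoters"))
write_stage_tsv(as.data.frame(cmp), "results/motif_incidence.tsv",
                "compare_incidence")
cat(sprintf("Motif incidence: %.1f%% in DMR promoters vs %.1f%% in %d random promoters (p = %.3g, %s)\n",
            100 * cmp$incidence[1], 100 * cmp$incidence[2],
            cmp$n_sequences[2], cmp$p_value[1], cmp$method[1]))

# cross-set overlap against an independently simulated DMR set
other <- plant_truth(generate_genome(seed = 77), n_dmrs = 20, seed = 77)$dmrs
ov <- overlap_dmr_sets(dmrs, other)
cat(nrow(ov), "of", nrow(dmrs),
    "DMRs overlap the independent comparison set\n")
write_stage_tsv(ov, "results/dmr_set_overlap.tsv", "overlap_dmr_sets")
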