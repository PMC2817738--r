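#!/usr/bin/env Rscript
# Step 1 — simulate the study genome.
#
# Builds a 1 Mb two-chromosome genome with isochore-like G+C states,
# 100 promoters whose surroundings are G+C-elevated (37% carrying an
# embedded CpG-island-like segment), poly-A tracts in the low-G+C
# background, and 80 TFBS annotations (a CTCF-like minority class will be
# depleted in the in vivo simulation). Everything is reproducible from the
# seed below; outputs land in results/dataset/ as FASTA + BED6.

suppressPackageStartupMessages(library(nucoccupancy))

seed <- 1L

cfg <- genome_sim_config(seed = derive_seed(seed, "genome"))
ds <- generate_genome(cfg)
print(ds)

save_dataset(ds, "results/dataset")

gc_all <- Biostrings::letterFrequency(ds$genome, "GC", as.prob = TRUE)
message(sprintf("genome G+C: %s", paste(sprintf("%s=%.3f",
        names(ds$genome), gc_all), collapse = ", ")))
message(sprintf("wrote results/dataset (%d TSS, %d islands, %d poly-A tracts, %d TFBS)",
        length(ds$tss), length(ds$islands), length(ds$polyA), length(ds$tfbs)))
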