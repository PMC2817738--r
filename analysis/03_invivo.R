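#!/usr/bin/env Rscript
# Step 3 — simulate the in vivo map and normalize both tracks.
#
# The in vivo-like coverage mixes the intrinsic track (alpha = 0.9) with
# block-wise log-normal trans-acting noise, multiplies the CTCF-like class
# down to 10%, and resamples everything as Poisson reads at 20x. Both tracks
# are then put on the paper-style scale: log2(value / genomic mean),
# re-centred so the genomic average is exactly zero (counts are floored at
# half the smallest positive value first).

suppressPackageStartupMessages(library(nucoccupancy))

seed <- 1L

genome <- Biostrings::readDNAStringSet("results/dataset/genome.fa")
genome_lengths <- stats::setNames(Biostrings::width(genome),
                                  sub(" .*", "", names(genome)))

intr <- load_track("results/intrinsic_raw.bedGraph", genome_lengths)
tfbs <- read_bed("results/dataset/tfbs.bed")
tfbs$class <- tfbs$name

cov <- simulate_invivo(intr, tfbs,
                       invivo_sim_config(alpha = 0.9, depletion = c(CTCF = 0.1),
                                         coverage = 20,
                                         seed = derive_seed(seed, "invivo")))
save_track(cov, "results/invivo_raw.bedGraph")

norm_i <- normalize_track(intr)
norm_v <- normalize_track(floor_track(cov))
save_track(norm_i, "results/intrinsic_norm.bedGraph")
save_track(norm_v, "results/invivo_norm.bedGraph")

message(sprintf("coverage mean %.2f; normalized means %.2g / %.2g (intrinsic / in vivo)",
        track_summary(cov)$genomic_mean,
        track_summary(norm_i)$genomic_mean,
        track_summary(norm_v)$genomic_mean))
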