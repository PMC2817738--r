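#!/usr/bin/env Rscript
# Step 4 — region sets and meta-profiles.
#
# Calls CpG islands directly on the simulated sequence, builds [-150, 0]
# proximal promoters, classifies them CpG / non-CpG by island overlap, and
# averages four tracks (normalized intrinsic, normalized in vivo, windowed
# G+C, windowed AAAA frequency) around the TSS of each promoter class and
# around non-promoter TFBS centers. Expectation from the construction: both
# occupancy tracks and G+C rise toward the TSS while poly-A falls, except
# that CTCF-like sites lose in vivo (not intrinsic) occupancy.

suppressPackageStartupMessages(library(nucoccupancy))

genome <- Biostrings::readDNAStringSet("results/dataset/genome.fa")
names(genome) <- sub(" .*", "", names(genome))
genome_lengths <- stats::setNames(Biostrings::width(genome), names(genome))

norm_i <- load_track("results/intrinsic_norm.bedGraph", genome_lengths)
norm_v <- load_track("results/invivo_norm.bedGraph", genome_lengths)
gc_tr <- window_stat_track(genome, "gc")
aa_tr <- window_stat_track(genome, "aaaa")

tss <- read_bed("results/dataset/tss.bed")
tfbs <- read_bed("results/dataset/tfbs.bed")

islands <- call_cpg_islands(genome)
write_bed(islands, "results/islands_called.bed")
prom <- classify_promoters_cpg(
  make_proximal_promoters(tss, 150, genome_lengths), islands)
message(sprintf("called %d islands; promoters: %d CpG, %d non-CpG",
        length(islands), sum(prom$cpg_class == "CpG"),
        sum(prom$cpg_class == "non-CpG")))

tfbs_np <- filter_nonpromoter(tfbs, tss, upstream = 1000,
                              chrom_lengths = genome_lengths)

anchor_sets <- list(
  promoter_cpg = list(gr = tss[prom$cpg_class == "CpG"], mode = "tss"),
  promoter_noncpg = list(gr = tss[prom$cpg_class == "non-CpG"], mode = "tss"),
  tfbs = list(gr = tfbs_np, mode = "center")
)
tracks <- list(intrinsic = norm_i, invivo = norm_v, gc = gc_tr, aaaa = aa_tr)

for (anm in names(anchor_sets)) {
  a <- anchor_sets[[anm]]
  if (length(a$gr) == 0) next
  for (tnm in names(tracks)) {
    p <- meta_profile(tracks[[tnm]], a$gr, flank = 1000, anchor_mode = a$mode)
    write_profile(p, sprintf("results/profile_%s_%s.tsv", anm, tnm))
  }
  message(sprintf("profiled %-16s (%d anchors)", anm, length(a$gr)))
}
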