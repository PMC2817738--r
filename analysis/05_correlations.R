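#!/usr/bin/env Rscript
# Step 5 — correlation structure and quadrant fractions.
#
# Relates normalized intrinsic to normalized in vivo occupancy base by base:
# genome-wide Pearson and Spearman, a Spearman on 1,000 positions per
# chromosome spaced >= 150 bases apart (the spacing breaks the nucleosome-
# scale autocorrelation that inflates naive significance), and the share of
# bases in each quadrant of the in vivo (x) vs intrinsic (y) plane around
# the genomic means. Also reports mean normalized occupancy per region class.

suppressPackageStartupMessages(library(nucoccupancy))

seed <- 1L

genome <- Biostrings::readDNAStringSet("results/dataset/genome.fa")
names(genome) <- sub(" .*", "", names(genome))
genome_lengths <- stats::setNames(Biostrings::width(genome), names(genome))

norm_i <- load_track("results/intrinsic_norm.bedGraph", genome_lengths)
norm_v <- load_track("results/invivo_norm.bedGraph", genome_lengths)
tss <- read_bed("results/dataset/tss.bed")
islands <- read_bed("results/islands_called.bed")
tfbs <- read_bed("results/dataset/tfbs.bed")

pear <- correlate_tracks(norm_i, norm_v, "pearson")
spear <- correlate_tracks(norm_i, norm_v, "spearman")
pos <- subsample_positions(norm_i, norm_v,
                           subsample_spec(1000L, 150L,
                                          seed = derive_seed(seed, "subsample")))
sub <- correlate_at_positions(norm_i, norm_v, pos, "spearman")

cors <- data.frame(
  which = c("pearson_all", "spearman_all", "spearman_subsampled"),
  r = c(pear$r, spear$r, sub$r),
  p = c(pear$p, spear$p, sub$p),
  n = c(pear$n, spear$n, sub$n)
)
write.table(cors, "results/correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(cors, row.names = FALSE)

quad <- quadrant_fractions(norm_v, norm_i)  # x = in vivo, y = intrinsic
write.table(data.frame(quadrant = names(quad$fractions),
                       fraction = unname(quad$fractions)),
            "results/quadrants.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
print(quad)
message("note: upper left (high intrinsic, depleted in vivo) outweighs lower right")

prom <- classify_promoters_cpg(
  make_proximal_promoters(tss, 150, genome_lengths), islands)
classes <- list(promoters = prom,
                promoters_cpg = prom[prom$cpg_class == "CpG"],
                promoters_noncpg = prom[prom$cpg_class == "non-CpG"],
                tfbs = tfbs)
rm_df <- do.call(rbind, lapply(names(classes), function(nm) {
  data.frame(region_class = nm, n = length(classes[[nm]]),
             mean_intrinsic = region_mean(norm_i, classes[[nm]]),
             mean_invivo = region_mean(norm_v, classes[[nm]]))
}))
write.table(rm_df, "results/region_means.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(rm_df, row.names = FALSE)
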