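# shared small dataset for the costlier checks
sim_cfg <- genome_sim_config(chrom_lengths = c(chr1 = 120000L, chr2 = 80000L),
                             promoter_count = 20L, tfbs_count = 24L, seed = 11)
sim_ds <- generate_genome(sim_cfg)

test_that("generation is byte-identical given the seed", {
  ds2 <- generate_genome(sim_cfg)
  expect_identical(as.character(sim_ds$genome), as.character(ds2$genome))
  expect_identical(as.data.frame(sim_ds$tss), as.data.frame(ds2$tss))
  expect_identical(as.data.frame(sim_ds$tfbs), as.data.frame(ds2$tfbs))
  ds3 <- generate_genome(genome_sim_config(
    chrom_lengths = c(chr1 = 120000L, chr2 = 80000L),
    promoter_count = 20L, tfbs_count = 24L, seed = 12))
  expect_false(identical(as.character(sim_ds$genome), as.character(ds3$genome)))
})

test_that("a one-state model recovers its G+C probability", {
  cfg <- genome_sim_config(chrom_lengths = c(chr1 = 1000000L),
                           state_gc = 0.5, state_mean_length = 10000,
                           state_cpg_suppression = 1,
                           promoter_count = 0L, tfbs_count = 0L,
                           polyA_rate = 0, cpg_island_fraction = 0, seed = 21)
  ds <- generate_genome(cfg)
  codes <- strsplit(as.character(ds$genome[[1]]), "")[[1]]
  gc <- mean(codes %in% c("C", "G"))
  expect_lt(abs(gc - 0.5), 0.002)  # 3 sigma binomial at 1 Mb
})

test_that("annotations stay within bounds and islands cover the proximal window", {
  for (nm in c("tss", "islands", "polyA", "tfbs")) {
    grx <- sim_ds[[nm]]
    if (length(grx) == 0) next
    lens <- sim_cfg$chrom_lengths[as.character(GenomeInfoDb::seqnames(grx))]
    expect_true(all(GenomicRanges::start(grx) >= 1))
    expect_true(all(GenomicRanges::end(grx) <= lens))
  }
  prom <- make_proximal_promoters(sim_ds$tss, 150, sim_cfg$chrom_lengths)
  # every ground-truth island overlaps some promoter window
  expect_true(all(IRanges::overlapsAny(sim_ds$islands, prom)))
})

test_that("zero island fraction leaves essentially all promoters island-free", {
  cfg <- genome_sim_config(chrom_lengths = c(chr1 = 400000L),
                           promoter_count = 40L, cpg_island_fraction = 0,
                           tfbs_count = 0L, seed = 31)
  ds <- generate_genome(cfg)
  expect_length(ds$islands, 0)
  isl <- call_cpg_islands(ds$genome)
  prom <- make_proximal_promoters(ds$tss, 150, cfg$chrom_lengths)
  clean <- 1 - mean(IRanges::overlapsAny(prom, isl))
  expect_gte(clean, 0.95)
})

test_that("poly-A tracts land in the low-G+C background", {
  expect_gt(length(sim_ds$polyA), 0)
  s <- as.character(sim_ds$genome)
  for (k in seq_along(sim_ds$polyA)) {
    ch <- as.character(GenomeInfoDb::seqnames(sim_ds$polyA))[k]
    frag <- substr(s[[ch]], GenomicRanges::start(sim_ds$polyA)[k],
                   GenomicRanges::end(sim_ds$polyA)[k])
    expect_true(frag == strrep("A", nchar(frag)) ||
                  frag == strrep("T", nchar(frag)))
  }
})

test_that("in vivo simulation is deterministic and near-noiseless at alpha = 1", {
  set.seed(91)
  n <- 100000
  base <- 0.5 + 0.4 * sin(seq_len(n) / 300)  # smooth track with wide range
  intr <- small_track(chr1 = base)
  cfg <- invivo_sim_config(alpha = 1, depletion = c(CTCF = 1),
                           coverage = 1000, seed = 41)
  cov1 <- simulate_invivo(intr, NULL, cfg)
  cov2 <- simulate_invivo(intr, NULL, cfg)
  expect_identical(cov1$values, cov2$values)
  r <- correlate_tracks(intr, cov1, "pearson")
  expect_gt(r$r, 0.99)
})

test_that("depleted TFBS classes lose coverage relative to their flanks", {
  set.seed(93)
  intr <- small_track(chr1 = rep(0.8, 200000))
  sites <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(seq(5000, 195000, by = 10000),
                                                   width = 100))
  sites$class <- "CTCF"
  flanks <- c(GenomicRanges::flank(sites, 500), GenomicRanges::flank(sites, 500, start = FALSE))
  ok <- 0
  for (k in 1:20) {
    cfg <- invivo_sim_config(alpha = 0.8, depletion = c(CTCF = 0.2),
                             coverage = 10, seed = k)
    cov <- simulate_invivo(intr, sites, cfg)
    if (region_mean(cov, sites) < region_mean(cov, flanks)) ok <- ok + 1
  }
  expect_equal(ok, 20)
})

test_that("low coverage produces the quantal regime", {
  set.seed(95)
  intr <- small_track(chr1 = runif(50000, 0.4, 1))
  cfg <- invivo_sim_config(alpha = 0.9, coverage = 0.5, seed = 7)
  cov <- simulate_invivo(intr, NULL, cfg)
  v <- cov$values$chr1
  expect_gte(mean(v %in% c(0, 1)), 0.5)
  expect_true(all(v == floor(v)))
})

test_that("alpha_for_rho inverts the generative correlation formula", {
  for (rho in c(0.1, 0.3, 0.5, 0.9)) {
    a <- alpha_for_rho(rho, sd_intrinsic = 0.25, sd_noise = 0.4)
    expect_equal(generative_rho(a, 0.25, 0.4), rho, tolerance = 1e-12)
  }
  expect_equal(generative_rho(1, 0.3, 0.5), 1)
  expect_equal(generative_rho(0, 0.3, 0.5), 0)
})

test_that("recovered correlation matches the analytic target", {
  # one mid-size genome, three target correlations
  cfg <- genome_sim_config(chrom_lengths = c(chr1 = 200000L),
                           promoter_count = 20L, tfbs_count = 0L, seed = 51)
  ds <- generate_genome(cfg)
  model <- fit_gc_model(ds$genome, n_windows = 1000, seed = 51)
  intr <- intrinsic_occupancy(ds$genome, model)
  iv <- unlist(intr$values)
  sd_i <- sd(iv); sd_eps <- invivo_noise_sd(mean(iv), 0.5)
  # short fragments: the coverage operator must not filter away the
  # nucleosome-scale variance of the intrinsic track for the alpha
  # calibration identity to be observable (see the methods vignette)
  for (rho in c(0.3, 0.5)) {
    a <- alpha_for_rho(rho, sd_i, sd_eps)
    cov <- simulate_invivo(intr, NULL,
                           invivo_sim_config(alpha = a, coverage = 2000,
                                             read_length = 5,
                                             noise_sdlog = 0.5, seed = 61))
    r <- correlate_tracks(intr, cov, "pearson")$r
    expect_lt(abs(r - rho), 0.05)
  }
})

test_that("datasets can be written out in standard formats", {
  dir <- withr::local_tempdir()
  save_dataset(sim_ds, dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  expect_true(file.exists(file.path(dir, "tss.bed")))
  expect_true(file.exists(file.path(dir, "params.txt")))
  g <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(sim_ds$genome))
  tss <- read_bed(file.path(dir, "tss.bed"))
  expect_equal(GenomicRanges::start(tss), GenomicRanges::start(sim_ds$tss))
})
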