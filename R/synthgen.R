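#' Configuration for the synthetic genome generator
#'
#' The generator emulates the statistical structure of mammalian genomic
#' input data: a two-state (isochore-like) regional G+C process, promoters
#' whose surroundings are G+C-elevated, a configurable fraction of promoters
#' carrying an embedded CpG-island-like segment (G+C-rich, CpG-enriched),
#' nucleosome-excluding poly-A tracts in the low-G+C state, and positional
#' TFBS annotations split into classes. CpG depletion outside islands is
#' imposed by a post-hoc pass that replaces the G of a CpG with A or T with
#' probability `1 - suppression`.
#'
#' @param chrom_lengths named integer vector (default two 500 kb
#'   chromosomes, 1 Mb total).
#' @param state_gc per-state G+C probability (low, high).
#' @param state_mean_length mean segment length per state, bases.
#' @param state_cpg_suppression per-state CpG retention probability.
#' @param promoter_count TSS count across the genome (default 100 per Mb;
#'   denser than the human genome so promoter statistics are stable at
#'   desk scale).
#' @param promoter_spacing minimum distance between TSSs, bases.
#' @param promoter_gc G+C probability of the promoter-proximal segment.
#' @param promoter_segment oriented interval around the TSS (relative
#'   coordinates) receiving `promoter_gc`.
#' @param promoter_cpg_suppression CpG retention in promoter segments
#'   outside islands.
#' @param cpg_island_fraction fraction of promoters with an embedded island
#'   (default 0.37, the human CpG-promoter share).
#' @param island_gc,island_length_range island segment G+C and length range;
#'   islands retain all CpGs.
#' @param polyA_rate per-base tract initiation rate in the low-G+C state.
#' @param polyA_min,polyA_mean_extra tract length = min + Geometric(mean
#'   extra).
#' @param tfbs_count,tfbs_width_range,tfbs_classes TFBS annotations: count,
#'   width range, and named class proportions (default 80% generic "TF",
#'   20% "CTCF"-like, the class targeted by in vivo depletion).
#' @param tfbs_gc,tfbs_flank G+C probability over each site plus `tfbs_flank`
#'   bases on either side — like real regulatory sites, TFBS neighbourhoods
#'   are G+C-elevated and hence intrinsically occupancy-prone.
#' @param seed master RNG seed.
#' @return a `GenomeSimConfig`.
#' @export
genome_sim_config <- function(chrom_lengths = c(chr1 = 500000L, chr2 = 500000L),
                              state_gc = c(0.37, 0.48),
                              state_mean_length = c(30000, 10000),
                              state_cpg_suppression = c(0.15, 0.15),
                              promoter_count = 100L,
                              promoter_spacing = 5000L,
                              promoter_gc = 0.55,
                              promoter_segment = c(-300L, 100L),
                              promoter_cpg_suppression = 0.15,
                              cpg_island_fraction = 0.37,
                              island_gc = 0.72,
                              island_length_range = c(500L, 1500L),
                              polyA_rate = 1 / 3000,
                              polyA_min = 5L,
                              polyA_mean_extra = 5,
                              tfbs_count = 80L,
                              tfbs_width_range = c(12L, 30L),
                              tfbs_classes = c(TF = 0.8, CTCF = 0.2),
                              tfbs_gc = 0.55,
                              tfbs_flank = 50L,
                              seed = 1L) {
  stopifnot(length(state_gc) == length(state_mean_length),
            length(state_gc) == length(state_cpg_suppression),
            all(state_gc >= 0 & state_gc <= 1),
            all(state_cpg_suppression >= 0 & state_cpg_suppression <= 1),
            all(state_mean_length >= 1),
            cpg_island_fraction >= 0, cpg_island_fraction <= 1,
            polyA_rate >= 0, polyA_min >= 1,
            abs(sum(tfbs_classes) - 1) < 1e-9)
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  n <- sum(chrom_lengths)
  if (promoter_count * (promoter_spacing + 4000) > n) {
    stop("infeasible placement: too many promoters for the genome size")
  }
  structure(as.list(environment()), class = "GenomeSimConfig")
}

#' Generate a synthetic genome with annotations
#'
#' Deterministic given the config seed: identical configs regenerate
#' byte-identical sequence and annotations.
#'
#' @param config a [genome_sim_config()].
#' @return a `SyntheticDataset`: list with `genome` (`DNAStringSet`), `tss`
#'   (stranded width-1 `GRanges`), `islands`, `polyA`, `tfbs` (`GRanges`,
#'   class in `$class`) and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "GenomeSimConfig"))
  set.seed(derive_seed(config$seed, "generate_genome"))
  chrom_lengths <- config$chrom_lengths
  genome_n <- sum(chrom_lengths)

  # promoter and TFBS counts per chromosome, proportional to length
  prom_per_chrom <- .split_count(config$promoter_count, chrom_lengths)
  tfbs_per_chrom <- .split_count(config$tfbs_count, chrom_lengths)

  seqs <- character(0)
  tss_l <- list(); isl_l <- list(); pa_l <- list(); tf_l <- list()
  for (ch in names(chrom_lengths)) {
    n <- as.integer(chrom_lengths[[ch]])
    st <- .sample_states(n, config$state_mean_length)
    gcp <- config$state_gc[st]
    supp <- config$state_cpg_suppression[st]

    # --- TSS placement (margin 2 kb from ends, minimum spacing) ---
    n_prom <- prom_per_chrom[[ch]]
    tss <- .spaced_positions(n_prom, lo = 2000L, hi = n - 2000L,
                             min_dist = config$promoter_spacing)
    strand <- sample(c("+", "-"), n_prom, replace = TRUE)
    sgn <- ifelse(strand == "+", 1L, -1L)

    # promoter-proximal G+C elevation, oriented by strand
    seg <- config$promoter_segment
    for (k in seq_len(n_prom)) {
      b <- sort(tss[k] + sgn[k] * seg)
      idx <- max(1L, b[1L]):min(n, b[2L])
      gcp[idx] <- config$promoter_gc
      supp[idx] <- config$promoter_cpg_suppression
    }

    # embedded CpG-island-like segments on a subset of promoters, covering
    # the proximal window (roughly [-0.75, +0.25] of the island length)
    has_island <- runif(n_prom) < config$cpg_island_fraction
    isl_s <- integer(0); isl_e <- integer(0)
    for (k in which(has_island)) {
      len <- as.integer(round(runif(1, config$island_length_range[1L],
                                    config$island_length_range[2L])))
      up <- as.integer(ceiling(0.75 * len))
      b <- sort(c(tss[k] - sgn[k] * up, tss[k] + sgn[k] * (len - up - 1L)))
      s <- max(1L, b[1L]); e <- min(n, b[2L])
      idx <- s:e
      gcp[idx] <- config$island_gc
      supp[idx] <- 1
      isl_s <- c(isl_s, s); isl_e <- c(isl_e, e)
    }

    # --- TFBS placement in the promoter-free background; like real
    # regulatory sites, their neighbourhood is G+C-elevated ---
    n_tf <- tfbs_per_chrom[[ch]]
    tf_s <- integer(0); tf_e <- integer(0)
    if (n_tf > 0) {
      widths <- as.integer(round(runif(n_tf, config$tfbs_width_range[1L],
                                       config$tfbs_width_range[2L])))
      cand <- .spaced_positions(n_tf, lo = 500L, hi = n - 500L, min_dist = 500L,
                                forbidden = .forbidden_mask(n, tss, margin = 1500L))
      tf_s <- cand
      tf_e <- pmin(n, cand + widths - 1L)
      for (k in seq_along(tf_s)) {
        idx <- max(1L, tf_s[k] - config$tfbs_flank):min(n, tf_e[k] + config$tfbs_flank)
        gcp[idx] <- config$tfbs_gc
      }
    }
    tf_class <- sample(names(config$tfbs_classes), n_tf, replace = TRUE,
                       prob = config$tfbs_classes)

    # --- emit sequence: per-base G+C probability, then CpG suppression ---
    u <- runif(n)
    is_gc <- u < gcp
    pick <- runif(n) < 0.5
    codes <- integer(n)
    codes[is_gc] <- ifelse(pick[is_gc], 2L, 3L)    # C or G
    codes[!is_gc] <- ifelse(pick[!is_gc], 1L, 4L)  # A or T
    gpos <- which(codes[-n] == 2L & codes[-1L] == 3L) + 1L
    if (length(gpos)) {
      drop <- runif(length(gpos)) >= supp[gpos]
      repl <- gpos[drop]
      codes[repl] <- ifelse(runif(length(repl)) < 0.5, 1L, 4L)
    }

    # --- poly-A tracts in the low-G+C state, outside promoter segments
    # and TFBS neighbourhoods ---
    low_state <- which.min(config$state_gc)
    keep <- st == low_state
    for (k in seq_along(tf_s)) {
      keep[max(1L, tf_s[k] - config$tfbs_flank):min(n, tf_e[k] + config$tfbs_flank)] <- FALSE
    }
    elig <- which(keep)
    pa_s <- integer(0); pa_e <- integer(0)
    if (length(elig) && config$polyA_rate > 0) {
      k_tracts <- rpois(1L, length(elig) * config$polyA_rate)
      if (k_tracts > 0) {
        starts <- sort(sample(elig, min(k_tracts, length(elig))))
        lens <- config$polyA_min +
          rgeom(length(starts), 1 / (config$polyA_mean_extra + 1))
        base <- ifelse(runif(length(starts)) < 0.5, 1L, 4L)  # A or T run
        for (k in seq_along(starts)) {
          e <- min(n, starts[k] + lens[k] - 1L)
          codes[starts[k]:e] <- base[k]
          pa_s <- c(pa_s, starts[k]); pa_e <- c(pa_e, e)
        }
      }
    }

    seqs[[ch]] <- codes_to_seq(codes)
    tss_l[[ch]] <- data.frame(chrom = rep(ch, length(tss)), pos = tss,
                              strand = strand)
    isl_l[[ch]] <- data.frame(chrom = rep(ch, length(isl_s)), start = isl_s,
                              end = isl_e)
    pa_l[[ch]] <- data.frame(chrom = rep(ch, length(pa_s)), start = pa_s,
                             end = pa_e)
    tf_l[[ch]] <- data.frame(chrom = rep(ch, length(tf_s)), start = tf_s,
                             end = tf_e, class = tf_class)
  }

  tssdf <- do.call(rbind, tss_l)
  isldf <- do.call(rbind, isl_l)
  padf <- do.call(rbind, pa_l)
  tfdf <- do.call(rbind, tf_l)
  mk <- function(df, stranded = FALSE) {
    gr <- GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end),
      strand = if (stranded) df$strand else rep("*", nrow(df)),
      seqlengths = chrom_lengths)
    gr
  }
  tss_gr <- GenomicRanges::GRanges(tssdf$chrom,
                                   IRanges::IRanges(tssdf$pos, width = 1L),
                                   strand = tssdf$strand,
                                   seqlengths = chrom_lengths)
  tfbs_gr <- mk(tfdf)
  tfbs_gr$class <- tfdf$class
  structure(list(
    genome = Biostrings::DNAStringSet(unlist(seqs)),
    tss = tss_gr,
    islands = mk(isldf),
    polyA = mk(padf),
    tfbs = tfbs_gr,
    config = config
  ), class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d chromosome(s), %d bases, %d TSS, %d islands, %d TFBS\n",
              length(x$genome), sum(Biostrings::width(x$genome)),
              length(x$tss), length(x$islands), length(x$tfbs)))
  invisible(x)
}

.split_count <- function(total, chrom_lengths) {
  w <- chrom_lengths / sum(chrom_lengths)
  k <- floor(total * w)
  rem <- total - sum(k)
  if (rem > 0) k[seq_len(rem)] <- k[seq_len(rem)] + 1
  stats::setNames(as.integer(k), names(chrom_lengths))
}

# alternating-state segmentation with geometric segment lengths
.sample_states <- function(n, mean_length) {
  ns <- length(mean_length)
  st <- integer(0)
  cur <- sample.int(ns, 1L, prob = mean_length / sum(mean_length))
  while (length(st) < n) {
    len <- 1L + rgeom(1L, 1 / mean_length[cur])
    st <- c(st, rep.int(cur, len))
    cur <- if (ns == 1L) cur else sample(setdiff(seq_len(ns), cur), 1L)
  }
  st[seq_len(n)]
}

.forbidden_mask <- function(n, tss, margin) {
  m <- rep(FALSE, n)
  for (t in tss) {
    m[max(1L, t - margin):min(n, t + margin)] <- TRUE
  }
  m
}

# rejection placement of k positions in [lo, hi] with pairwise spacing and
# an optional forbidden mask
.spaced_positions <- function(k, lo, hi, min_dist, forbidden = NULL) {
  if (k == 0L) return(integer(0))
  if (hi < lo) stop("infeasible placement: chromosome too short")
  taken <- integer(0)
  blocked <- rep(FALSE, hi)
  attempts <- 0L
  cap <- 1000L * k
  while (length(taken) < k && attempts < cap) {
    attempts <- attempts + 1L
    p <- as.integer(floor(runif(1, lo, hi + 1)))
    if (blocked[p] || (!is.null(forbidden) && forbidden[p])) next
    taken <- c(taken, p)
    blocked[max(1L, p - min_dist):min(hi, p + min_dist)] <- TRUE
  }
  if (length(taken) < k) stop("infeasible placement: too many elements")
  sort(taken)
}

#' Configuration for the in vivo-like coverage simulator
#'
#' @param alpha mixing weight in \[0, 1\] between intrinsic occupancy and
#'   independent noise in the latent occupancy.
#' @param depletion named multiplicative depletion factors per annotation
#'   class (applied to latent occupancy over those sites; default 0.2 for
#'   the CTCF-like class, emulating trans-factor exclusion).
#' @param coverage expected reads-per-base depth `c`; low values produce the
#'   quantal few-distinct-values artifact of real low-coverage maps.
#' @param read_length fragment length used to smooth read starts into
#'   per-base coverage.
#' @param noise_sdlog log-normal sdlog of the noise component.
#' @param noise_block block length (bases) over which the noise is constant;
#'   models regional trans-acting variation rather than per-base white noise.
#' @param seed RNG seed.
#' @export
invivo_sim_config <- function(alpha = 0.8,
                              depletion = c(CTCF = 0.2),
                              coverage = 20,
                              read_length = 50L,
                              noise_sdlog = 0.5,
                              noise_block = 200L,
                              seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (coverage <= 0) stop("coverage must be > 0")
  if (any(depletion <= 0)) stop("depletion factors must be > 0")
  structure(as.list(environment()), class = "InVivoSimConfig")
}

#' Simulate an in vivo-like nucleosome coverage track
#'
#' Latent occupancy is
#' `lambda(i) = (alpha * intrinsic(i) + (1 - alpha) * eps(i)) * depletion(class(i))`
#' with `eps` positive block-constant log-normal noise scaled to the
#' intrinsic track's mean. Read starts are Poisson with per-base expectation
#' proportional to `coverage * lambda(i)` (normalized so mean coverage is
#' about `coverage`), and the output is per-base read coverage: integer
#' counts smoothed by the read length, so low-coverage outputs take few
#' distinct values (quantal).
#'
#' @param intrinsic a `GenomeTrack` of intrinsic occupancy in \[0, 1\].
#' @param annotations a `GRanges` with a `class` metadata column (e.g. the
#'   `tfbs` element of a `SyntheticDataset`), or `NULL` for no depletion.
#' @param config an [invivo_sim_config()].
#' @return a `GenomeTrack` of integer coverage, with attribute `lambda` (the
#'   latent per-chromosome occupancy used, for recovery diagnostics).
#' @export
simulate_invivo <- function(intrinsic, annotations, config) {
  stopifnot(inherits(intrinsic, "GenomeTrack"),
            inherits(config, "InVivoSimConfig"))
  if (config$alpha < 0 || config$alpha > 1) stop("alpha must be in [0, 1]")
  if (config$coverage <= 0) stop("coverage must be > 0")
  vall <- unlist(intrinsic$values, use.names = FALSE)
  if (any(vall < 0 | vall > 1, na.rm = TRUE)) {
    stop("intrinsic values must lie in [0, 1]")
  }
  mean_i <- mean(vall, na.rm = TRUE)
  rl <- as.integer(config$read_length)
  out <- list(); lambdas <- list()
  for (ch in names(intrinsic$values)) {
    set.seed(derive_seed(config$seed, paste0("invivo:", ch)))
    v <- intrinsic$values[[ch]]
    n <- length(v)
    iv <- ifelse(is.na(v), mean_i, v)
    nb <- ceiling(n / config$noise_block)
    eps <- mean_i * rep(rlnorm(nb, meanlog = -config$noise_sdlog^2 / 2,
                               sdlog = config$noise_sdlog),
                        each = config$noise_block)[seq_len(n)]
    lambda <- config$alpha * iv + (1 - config$alpha) * eps
    if (!is.null(annotations) && length(annotations)) {
      chs <- as.character(GenomeInfoDb::seqnames(annotations))
      for (cl in names(config$depletion)) {
        sel <- chs == ch & annotations$class == cl
        if (any(sel)) {
          st <- GenomicRanges::start(annotations)[sel]
          en <- GenomicRanges::end(annotations)[sel]
          for (k in seq_along(st)) {
            idx <- max(1L, st[k]):min(n, en[k])
            lambda[idx] <- lambda[idx] * config$depletion[[cl]]
          }
        }
      }
    }
    lambda[lambda < 0] <- 0
    S <- n - rl + 1L
    if (S < 1L) stop("read_length exceeds chromosome ", ch)
    rate <- config$coverage * lambda[seq_len(S)] / (mean(lambda) * rl)
    counts <- rpois(S, rate)
    cs <- c(0, cumsum(counts))
    j <- seq_len(n)
    cov <- cs[pmin(j, S) + 1L] - cs[pmax(j - rl, 0L) + 1L]
    out[[ch]] <- as.numeric(cov)
    lambdas[[ch]] <- lambda
  }
  tr <- genome_track(out)
  attr(tr, "lambda") <- lambdas
  tr
}

#' Mixing weight for a target generative correlation
#'
#' For latent occupancy `alpha * I + (1 - alpha) * eps` with independent
#' noise, the Pearson correlation with `I` is
#' `rho = alpha * sd_I / sqrt(alpha^2 sd_I^2 + (1 - alpha)^2 sd_eps^2)`.
#' Solving for `alpha` gives
#' `alpha = rho * sd_eps / (sd_I * sqrt(1 - rho^2) + rho * sd_eps)`.
#'
#' @param rho target correlation in (0, 1).
#' @param sd_intrinsic standard deviation of the intrinsic track (measure it
#'   on the realized track).
#' @param sd_noise standard deviation of the noise component, i.e.
#'   `mean_I * sqrt(exp(sdlog^2) - 1)` for the log-normal noise.
#' @return the mixing weight `alpha`.
#' @rdname generative_rho
#' @export
alpha_for_rho <- function(rho, sd_intrinsic, sd_noise) {
  stopifnot(rho > 0, rho < 1, sd_intrinsic > 0, sd_noise > 0)
  rho * sd_noise / (sd_intrinsic * sqrt(1 - rho^2) + rho * sd_noise)
}

#' @param alpha mixing weight in \[0, 1\].
#' @rdname generative_rho
#' @export
generative_rho <- function(alpha, sd_intrinsic, sd_noise) {
  a <- alpha * sd_intrinsic
  b <- (1 - alpha) * sd_noise
  a / sqrt(a^2 + b^2)
}

#' Standard deviation of the log-normal noise component
#' @param mean_intrinsic mean of the intrinsic track.
#' @param sdlog log-normal sdlog (see [invivo_sim_config()]).
#' @export
invivo_noise_sd <- function(mean_intrinsic, sdlog) {
  mean_intrinsic * sqrt(exp(sdlog^2) - 1)
}

#' Write a synthetic dataset to disk in standard formats
#'
#' FASTA genome, BED6 per annotation class, and a plain-text parameter file
#' capturing every config field plus the seed (sufficient to regenerate the
#' dataset byte-identically).
#'
#' @param dataset a `SyntheticDataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(dataset$genome, file.path(dir, "genome.fa"))
  write_bed(dataset$tss, file.path(dir, "tss.bed"))
  for (nm in c("islands", "polyA", "tfbs")) {
    gr <- dataset[[nm]]
    if (!is.null(gr$class)) gr$name <- gr$class  # BED column 4
    if (length(gr)) write_bed(gr, file.path(dir, paste0(nm, ".bed")))
  }
  cfg <- dataset$config
  lines <- vapply(names(cfg), function(k) {
    sprintf("%s = %s", k, paste(deparse(cfg[[k]]), collapse = " "))
  }, character(1))
  writeLines(lines, file.path(dir, "params.txt"))
  invisible(dir)
}
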