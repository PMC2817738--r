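#' Fit a nucleosome model from G+C-rich windows of a genome
#'
#' Stand-in training procedure for an externally trained occupancy model:
#' samples `n_windows` random `L`-base windows, takes the `top_frac` most
#' G+C-rich as the bound set and all sampled windows as background. On
#' genomes where regulatory sequence is G+C-elevated this yields a model
#' that, like the published human-genome scores, prefers G+C-rich sequence
#' and penalizes poly-A.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param L footprint length (default 147).
#' @param n_windows windows sampled (default 2000).
#' @param top_frac fraction retained as bound (default 0.2).
#' @param pseudocount fitting pseudocount.
#' @param seed RNG seed.
#' @return a `NucleosomeModel`.
#' @export
fit_gc_model <- function(genome, L = 147L, n_windows = 2000L, top_frac = 0.2,
                         pseudocount = 1, seed = 1L) {
  seqs <- as_genome_seqs(genome)
  set.seed(derive_seed(seed, "fit_gc_model"))
  lens <- nchar(seqs)
  keep <- lens >= L
  if (!any(keep)) stop("no chromosome long enough for a window of length ", L)
  seqs <- seqs[keep]; lens <- lens[keep]
  probs <- (lens - L + 1) / sum(lens - L + 1)
  chs <- sample(names(seqs), n_windows, replace = TRUE, prob = probs)
  wins <- character(0)
  for (ch in names(seqs)) {
    k <- sum(chs == ch)
    if (k == 0L) next
    starts <- sample.int(lens[[ch]] - L + 1L, k, replace = TRUE)
    wins <- c(wins, substring(seqs[[ch]], starts, starts + L - 1L))
  }
  wins <- wins[!grepl("[^ACGTacgt]", wins)]
  if (length(wins) < 10L) stop("too few unambiguous windows sampled")
  gc <- vapply(wins, function(w) {
    cd <- seq_to_codes(w); mean(cd == 2L | cd == 3L)
  }, numeric(1), USE.NAMES = FALSE)
  bound <- wins[gc >= stats::quantile(gc, 1 - top_frac)]
  fit_nucleosome_model(toupper(bound), toupper(wins), pseudocount = pseudocount, L = L)
}

#' Mean track value over a region set
#'
#' @param track a `GenomeTrack`.
#' @param regions a `GRanges`.
#' @return mean of defined values over all region bases.
#' @export
region_mean <- function(track, regions) {
  stopifnot(inherits(track, "GenomeTrack"), methods::is(regions, "GRanges"))
  tot <- 0; cnt <- 0L
  chs <- as.character(GenomeInfoDb::seqnames(regions))
  for (ch in unique(chs)) {
    v <- track$values[[ch]]
    if (is.null(v)) next
    sel <- chs == ch
    st <- pmax(1L, GenomicRanges::start(regions)[sel])
    en <- pmin(length(v), GenomicRanges::end(regions)[sel])
    w <- en - st + 1L
    ok <- w > 0L
    if (!any(ok)) next
    idx <- sequence(w[ok], from = st[ok])
    vals <- v[idx]
    tot <- tot + sum(vals, na.rm = TRUE)
    cnt <- cnt + sum(!is.na(vals))
  }
  if (cnt == 0L) return(NA_real_)
  tot / cnt
}

#' End-to-end pipeline configuration
#'
#' @param genome_config a [genome_sim_config()] (simulate), or `NULL` when
#'   `dataset` is supplied.
#' @param invivo_config an [invivo_sim_config()].
#' @param dataset optionally a pre-built `SyntheticDataset`.
#' @param model a `NucleosomeModel`, or `NULL` to fit one with
#'   [fit_gc_model()].
#' @param L,model_windows model-fitting parameters when `model` is `NULL`.
#' @param mu chemical potential (`NULL` = calibrate to `target_occupancy`).
#' @param target_occupancy calibration target (default 0.8).
#' @param flank meta-profile half-width (default 1000).
#' @param subsample a [subsample_spec()], or `NULL` to skip subsampling.
#' @param x_split,y_split quadrant thresholds on the normalized tracks.
#' @param outdir output directory for artifacts, or `NULL` for none.
#' @param seed master seed; stage seeds derive from it.
#' @export
pipeline_config <- function(genome_config = genome_sim_config(),
                            invivo_config = invivo_sim_config(),
                            dataset = NULL,
                            model = NULL, L = 147L, model_windows = 2000L,
                            mu = NULL, target_occupancy = 0.8,
                            flank = 1000L,
                            subsample = subsample_spec(n_per_chrom = 1000L,
                                                       min_dist = 150L),
                            x_split = 0, y_split = 0,
                            outdir = NULL, seed = 1L) {
  if (is.null(dataset) && is.null(genome_config)) {
    stop("either a dataset or a genome_config is required")
  }
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the end-to-end intrinsic-occupancy analysis
#'
#' Stages, in dependency order: simulate (or take) the genome and
#' annotations; fit/score the nucleosome model and predict intrinsic
#' occupancy; simulate the in vivo-like coverage; floor and normalize both
#' tracks; build promoter sets and classify them against called CpG
#' islands; compute meta-profiles per region class; compute all-bases and
#' subsampled correlations and quadrant fractions. Identical (config, seed)
#' yield identical reports. With `outdir` set, intermediate artifacts are
#' written in their standard formats (FASTA/BED6/bedGraph/TSV).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return a `RunReport` (list): `dataset`, `model`, `mu`, `tracks`
#'   (normalized intrinsic and in vivo), `correlations`, `quadrants`,
#'   `region_means`, `profiles`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (!quiet) message("[pipeline] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ds <- stage("simulate", {
    if (!is.null(config$dataset)) config$dataset else {
      gc <- config$genome_config
      gc$seed <- derive_seed(config$seed, "genome")
      say("simulating genome (%d bp)", sum(gc$chrom_lengths))
      generate_genome(gc)
    }
  })

  model <- stage("model", {
    if (!is.null(config$model)) config$model else {
      say("fitting G+C model (L = %d)", config$L)
      fit_gc_model(ds$genome, L = config$L, n_windows = config$model_windows,
                   seed = derive_seed(config$seed, "model"))
    }
  })

  say("scoring intrinsic occupancy")
  intr <- stage("score", {
    intrinsic_occupancy(ds$genome, model, mu = config$mu,
                        target_occupancy = config$target_occupancy)
  })
  mu <- attr(intr, "mu")

  say("simulating in vivo coverage")
  invivo <- stage("invivo", {
    ic <- config$invivo_config
    ic$seed <- derive_seed(config$seed, "invivo")
    simulate_invivo(intr, ds$tfbs, ic)
  })

  say("normalizing tracks")
  norm <- stage("normalize", {
    list(intrinsic = normalize_track(intr),
         invivo = normalize_track(suppressMessages(floor_track(invivo))))
  })

  say("building region sets")
  chrom_lengths <- track_lengths(intr)
  regions <- stage("regions", {
    prom <- make_proximal_promoters(ds$tss, upstream = 150,
                                    chrom_lengths = chrom_lengths)
    islands <- call_cpg_islands(ds$genome)
    prom <- classify_promoters_cpg(prom, islands)
    list(promoters = prom, islands = islands,
         tfbs = filter_nonpromoter(ds$tfbs, ds$tss, upstream = 1000,
                                   chrom_lengths = chrom_lengths))
  })

  say("computing meta-profiles")
  profiles <- stage("profiles", {
    prom <- regions$promoters
    out <- list()
    for (cls in c("CpG", "non-CpG")) {
      sel <- ds$tss[prom$cpg_class == cls]
      if (length(sel)) {
        out[[paste0("promoter_", cls)]] <-
          meta_profile(norm$intrinsic, sel, flank = config$flank,
                       anchor_mode = "tss")
      }
    }
    if (length(regions$tfbs)) {
      out$tfbs <- meta_profile(norm$intrinsic, regions$tfbs,
                               flank = config$flank, anchor_mode = "center")
    }
    out
  })

  say("correlating tracks")
  correlations <- stage("correlate", {
    res <- list(
      pearson = correlate_tracks(norm$intrinsic, norm$invivo, "pearson"),
      spearman = correlate_tracks(norm$intrinsic, norm$invivo, "spearman")
    )
    if (!is.null(config$subsample)) {
      sp <- config$subsample
      sp$seed <- derive_seed(config$seed, "subsample")
      pos <- subsample_positions(norm$intrinsic, norm$invivo, sp)
      res$subsampled <- correlate_at_positions(norm$intrinsic, norm$invivo,
                                               pos, "spearman")
      res$positions <- pos
    }
    res
  })

  quadrants <- stage("quadrants", {
    # oriented as the joint scatter is conventionally drawn: in vivo on x,
    # intrinsic on y, so "upper left" = high intrinsic but depleted in vivo
    quadrant_fractions(norm$invivo, norm$intrinsic,
                       x_split = config$x_split, y_split = config$y_split)
  })

  region_means <- stage("region_means", {
    prom <- regions$promoters
    classes <- list(
      promoters = prom,
      promoters_cpg = prom[prom$cpg_class == "CpG"],
      promoters_noncpg = prom[prom$cpg_class == "non-CpG"],
      tfbs = regions$tfbs
    )
    do.call(rbind, lapply(names(classes), function(nm) {
      data.frame(region_class = nm, n = length(classes[[nm]]),
                 mean_intrinsic = region_mean(norm$intrinsic, classes[[nm]]),
                 mean_invivo = region_mean(norm$invivo, classes[[nm]]))
    }))
  })

  report <- structure(list(
    dataset = ds, model = model, mu = mu,
    tracks = norm, intrinsic_raw = intr, invivo_raw = invivo,
    regions = regions, profiles = profiles,
    correlations = correlations, quadrants = quadrants,
    region_means = region_means, seed = config$seed
  ), class = "RunReport")

  if (!is.null(config$outdir)) {
    say("writing artifacts to %s", config$outdir)
    stage("write", write_report(report, config$outdir))
  }
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport\n")
  cat(sprintf("  mu = %.4f\n", x$mu))
  cat(sprintf("  pearson r = %.4f (n = %d), spearman r = %.4f\n",
              x$correlations$pearson$r, x$correlations$pearson$n,
              x$correlations$spearman$r))
  if (!is.null(x$correlations$subsampled)) {
    cat(sprintf("  subsampled spearman r = %.4f (n = %d, p = %.3g)\n",
                x$correlations$subsampled$r, x$correlations$subsampled$n,
                x$correlations$subsampled$p))
  }
  cat("  quadrant fractions:\n")
  print(round(x$quadrants$fractions, 4))
  cat("  region means (normalized):\n")
  print(x$region_means, row.names = FALSE)
  invisible(x)
}

#' Write the report's tables and tracks to a directory
#'
#' @param report a `RunReport`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_dataset(report$dataset, file.path(dir, "dataset"))
  write_model(report$model, file.path(dir, "model.txt"))
  save_track(report$tracks$intrinsic, file.path(dir, "intrinsic_norm.bedGraph"))
  save_track(report$tracks$invivo, file.path(dir, "invivo_norm.bedGraph"))
  for (nm in names(report$profiles)) {
    write_profile(report$profiles[[nm]],
                  file.path(dir, sprintf("profile_%s.tsv", gsub("[^A-Za-z0-9_]", "_", nm))))
  }
  cor_df <- do.call(rbind, lapply(c("pearson", "spearman", "subsampled"), function(nm) {
    cr <- report$correlations[[nm]]
    if (is.null(cr)) return(NULL)
    data.frame(which = nm, method = cr$method, r = cr$r, p = cr$p, n = cr$n)
  }))
  utils::write.table(cor_df, file.path(dir, "correlations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  qd <- data.frame(quadrant = names(report$quadrants$fractions),
                   fraction = unname(report$quadrants$fractions))
  utils::write.table(qd, file.path(dir, "quadrants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$region_means, file.path(dir, "region_means.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary_lines <- utils::capture.output(print(report))
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
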