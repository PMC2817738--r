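#' Thermodynamic occupancy from an energy landscape
#'
#' Computes the equilibrium probability that each base is covered by a
#' nucleosome under a grand-canonical ensemble of non-overlapping `L`-base
#' footprints. A configuration (a set of non-overlapping footprint starts)
#' has statistical weight `prod(exp(mu - E(i)))`; the empty configuration has
#' weight 1. Start probabilities come from linear-time forward/backward
#' recursions over the partition function, carried in log space so that
#' chromosome-scale inputs with |E| <= 50 cannot overflow. Masked starts get
#' weight 0, and bases coverable by no valid footprint have occupancy 0.
#'
#' @param landscape an `EnergyLandscape` from [score_energies()], or a bare
#'   numeric vector of energies (then `n_bases = length + L - 1`).
#' @param mu chemical potential; higher mu means denser packing.
#' @param L footprint length in bases.
#' @return an `OccupancyResult`: list with `occupancy` (per base, in
#'   \[0, 1\]), `p_start` (per footprint start), `log_partition` and `mu`.
#' @examples
#' # 3 bases, L = 2, all energies 0, mu = 0: configurations {}, {1}, {2}
#' r <- occupancy_from_energies(c(0, 0), mu = 0, L = 2)
#' r$occupancy           # 1/3, 2/3, 1/3
#' exp(r$log_partition)  # 3
#' @export
occupancy_from_energies <- function(landscape, mu, L) {
  if (inherits(landscape, "EnergyLandscape")) {
    e <- landscape$energies
    n <- landscape$n_bases
    if (length(e) > 0L && length(e) != n - L + 1L) {
      stop("landscape start count does not match n_bases - L + 1")
    }
  } else {
    e <- as.numeric(landscape)
    n <- length(e) + L - 1L
  }
  if (any(!is.finite(e) & !is.na(e))) {
    stop("non-finite energy at unmasked start")
  }
  logw <- mu - e
  logw[is.na(logw)] <- -Inf
  res <- occupancy_dp(logw, as.integer(L), as.integer(n))
  structure(list(occupancy = res$occupancy, p_start = res$p_start,
                 log_partition = res$log_partition, mu = mu),
            class = "OccupancyResult")
}

#' Predict intrinsic nucleosome occupancy across a genome
#'
#' Per-chromosome composition of [score_energies()] and
#' [occupancy_from_energies()]. Chromosomes are independent; bases within
#' `L - 1` of a chromosome end or an N-run carry correspondingly reduced
#' coverable mass, and bases with no coverable footprint are defined with
#' value 0 (not masked), so downstream normalization masks stay explicit.
#'
#' @param genome a `DNAStringSet` or named character vector of chromosome
#'   sequences.
#' @param model a `NucleosomeModel`.
#' @param mu chemical potential; `NULL` (default) calibrates it so the
#'   genome-mean occupancy equals `target_occupancy`.
#' @param target_occupancy calibration target used when `mu` is `NULL`.
#' @return a [genome_track()] of per-base occupancy with attribute `mu`.
#' @export
intrinsic_occupancy <- function(genome, model, mu = NULL, target_occupancy = 0.8) {
  seqs <- as_genome_seqs(genome)
  if (length(seqs) == 0L) stop("genome is empty")
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    warning("skipping zero-length chromosome(s): ",
            paste(names(seqs)[empty], collapse = ", "))
    seqs <- seqs[!empty]
    if (length(seqs) == 0L) stop("genome is empty")
  }
  landscapes <- lapply(names(seqs), function(ch) {
    score_energies(seqs[[ch]], model, chrom = ch)
  })
  names(landscapes) <- names(seqs)
  if (is.null(mu)) {
    mu <- calibrate_mu(landscapes, L = model$L, target = target_occupancy)
  }
  values <- lapply(landscapes, function(l) {
    occupancy_from_energies(l, mu = mu, L = model$L)$occupancy
  })
  track <- genome_track(values)
  attr(track, "mu") <- mu
  track
}
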