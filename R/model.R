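#' Fit a position-specific dinucleotide nucleosome model
#'
#' The model scores an `L`-base footprint by its dinucleotide content at each
#' of the `L - 1` footprint positions, relative to a position-free background.
#' Fitting counts dinucleotides over the bound windows *and their reverse
#' complements* (nucleosomes are strand-agnostic, so the model is
#' strand-symmetric by construction), adds `pseudocount` to every cell and
#' normalizes per position. The background is fit the same way over all
#' dinucleotides of the background sequences.
#'
#' @param bound_windows character vector of nucleosome-bound sequences, each
#'   exactly `L` bases over A/C/G/T.
#' @param background_seqs character vector of background sequences (any
#'   length >= 2); at least one required.
#' @param pseudocount nonnegative count added to every dinucleotide cell.
#' @param L footprint length in bases (default 147, the canonical nucleosome
#'   core particle); inferred from the windows when omitted.
#' @return an object of class `NucleosomeModel` with fields `L`,
#'   `dinuc_logprob` ((L-1) x 16 matrix of log probabilities), `bg_logprob`
#'   (16 log probabilities) and `pseudocount`.
#' @examples
#' m <- fit_nucleosome_model(c("AATT", "AATT"), c("ACGTACGT"), pseudocount = 1)
#' exp(m$dinuc_logprob[1, "AA"])  # 0.25
#' @export
fit_nucleosome_model <- function(bound_windows, background_seqs,
                                 pseudocount = 1, L = NULL) {
  if (length(bound_windows) == 0L) stop("empty bound window set")
  if (length(background_seqs) == 0L) stop("at least one background sequence is required")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (is.null(L)) L <- nchar(bound_windows[[1L]])
  if (L < 2L) stop("L must be >= 2")
  bad <- which(nchar(bound_windows) != L)
  if (length(bad)) {
    stop(sprintf("bound window %d has length %d, expected L = %d",
                 bad[1L], nchar(bound_windows[bad[1L]]), L))
  }

  counts <- matrix(0, nrow = L - 1L, ncol = 16L,
                   dimnames = list(NULL, .DINUCS))
  add_window <- function(w) {
    d <- dinuc_codes(seq_to_codes(w))
    if (anyNA(d)) stop("bound windows must contain only A/C/G/T")
    counts[cbind(seq_len(L - 1L), d)] <<- counts[cbind(seq_len(L - 1L), d)] + 1
  }
  for (w in bound_windows) {
    add_window(w)
    add_window(revcomp(w))
  }
  counts <- counts + pseudocount
  dinuc_logprob <- log(counts / rowSums(counts))

  bg_counts <- stats::setNames(rep(0, 16L), .DINUCS)
  for (s in background_seqs) {
    for (x in c(s, revcomp(s))) {
      d <- dinuc_codes(seq_to_codes(x))
      d <- d[!is.na(d)]
      if (length(d)) {
        t <- tabulate(d, nbins = 16L)
        bg_counts <- bg_counts + t
      }
    }
  }
  bg_counts <- bg_counts + pseudocount
  if (sum(bg_counts) == 0) stop("background sequences contain no dinucleotides")
  bg_logprob <- log(bg_counts / sum(bg_counts))

  structure(
    list(L = as.integer(L), dinuc_logprob = dinuc_logprob,
         bg_logprob = bg_logprob, pseudocount = pseudocount),
    class = "NucleosomeModel"
  )
}

#' @export
print.NucleosomeModel <- function(x, ...) {
  cat(sprintf("NucleosomeModel: L = %d, pseudocount = %g\n", x$L, x$pseudocount))
  lo <- log_odds(x)
  cat(sprintf("  log-odds range: [%.3f, %.3f]\n", min(lo), max(lo)))
  invisible(x)
}

#' Per-position dinucleotide log-odds of a model
#'
#' @param model a `NucleosomeModel`.
#' @return an (L-1) x 16 matrix `dinuc_logprob - bg_logprob`.
#' @export
log_odds <- function(model) {
  stopifnot(inherits(model, "NucleosomeModel"))
  sweep(model$dinuc_logprob, 2L, model$bg_logprob, "-")
}

#' Write / read a nucleosome model as a flat text table
#'
#' One row per (footprint position, dinucleotide) plus a header carrying `L`
#' and the pseudocount; the background is stored at position 0.
#'
#' @param model a `NucleosomeModel`.
#' @param path file path.
#' @rdname model_io
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "NucleosomeModel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nucleosome-model L=%d pseudocount=%.17g",
                     model$L, model$pseudocount), con)
  df <- rbind(
    data.frame(position = 0L, dinucleotide = .DINUCS,
               logprob = unname(model$bg_logprob)),
    data.frame(position = rep(seq_len(model$L - 1L), each = 16L),
               dinucleotide = rep(.DINUCS, model$L - 1L),
               logprob = as.vector(t(model$dinuc_logprob)))
  )
  utils::write.table(format(df, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' @rdname model_io
#' @export
read_model <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("L=([0-9]+) pseudocount=([0-9.eE+-]+)", header))[[1L]]
  if (length(m) != 3L) stop("not a nucleosome model file: ", path)
  L <- as.integer(m[2L])
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  bg <- df[df$position == 0L, ]
  bg_logprob <- stats::setNames(bg$logprob, bg$dinucleotide)[.DINUCS]
  dl <- matrix(NA_real_, L - 1L, 16L, dimnames = list(NULL, .DINUCS))
  body <- df[df$position > 0L, ]
  dl[cbind(body$position, match(body$dinucleotide, .DINUCS))] <- body$logprob
  structure(list(L = L, dinuc_logprob = dl, bg_logprob = bg_logprob,
                 pseudocount = as.numeric(m[3L])),
            class = "NucleosomeModel")
}

#' Score footprint binding energies along a sequence
#'
#' For each footprint start `i`, the log-likelihood ratio of the window under
#' the nucleosome vs. background model is computed for the forward window and
#' for its reverse complement; the energy is `E(i) = -(llr_fwd + llr_rc) / 2`,
#' so favourable sequence means low energy. Windows containing ambiguous
#' bases are masked.
#'
#' @param sequence a DNA string (A/C/G/T/N, case-insensitive).
#' @param model a `NucleosomeModel`.
#' @param chrom chromosome label attached to the landscape.
#' @return an `EnergyLandscape`: list with `chrom`, `energies` (length
#'   `nchar(sequence) - L + 1`, `NA` at masked starts), `mask` (logical,
#'   `TRUE` = masked) and `n_bases`.
#' @export
score_energies <- function(sequence, model, chrom = "chr") {
  stopifnot(inherits(model, "NucleosomeModel"))
  L <- model$L
  n <- nchar(sequence)
  if (n < L) {
    return(structure(list(chrom = chrom, energies = numeric(0),
                          mask = logical(0), n_bases = n),
                     class = "EnergyLandscape"))
  }
  lo <- log_odds(model)
  llr_fwd <- .window_llr(sequence, lo, L)
  llr_rc_all <- .window_llr(revcomp(sequence), lo, L)
  # the reverse complement of the window starting at i is the window of
  # revcomp(sequence) starting at the mirrored index S - i + 1
  llr_rc <- rev(llr_rc_all)
  e <- -0.5 * (llr_fwd + llr_rc)
  structure(list(chrom = chrom, energies = e, mask = is.na(e), n_bases = n),
            class = "EnergyLandscape")
}

# vectorized sum of per-position dinucleotide log-odds over all windows
.window_llr <- function(sequence, lo, L) {
  codes <- seq_to_codes(sequence)
  d <- dinuc_codes(codes)
  S <- length(codes) - L + 1L
  acc <- numeric(S)
  for (p in seq_len(L - 1L)) {
    lo_p <- unname(lo[p, ])
    acc <- acc + lo_p[d[p:(p + S - 1L)]]
  }
  acc
}

#' Calibrate the chemical potential to a target mean occupancy
#'
#' Mean occupancy is monotone nondecreasing in the chemical potential, so a
#' root search sets the genome-average occupancy to `target`.
#'
#' @param landscapes a list of `EnergyLandscape` objects (one per chromosome).
#' @param L footprint length.
#' @param target target genome-mean occupancy (default 0.8, mimicking dense
#'   eukaryotic chromatin).
#' @param interval search interval for mu.
#' @return the calibrated chemical potential (scalar).
#' @export
calibrate_mu <- function(landscapes, L, target = 0.8, interval = c(-60, 60)) {
  if (inherits(landscapes, "EnergyLandscape")) landscapes <- list(landscapes)
  total_bases <- sum(vapply(landscapes, function(l) l$n_bases, numeric(1)))
  if (total_bases == 0) stop("no bases to calibrate on")
  f <- function(mu) {
    s <- 0
    for (l in landscapes) {
      occ <- occupancy_from_energies(l, mu = mu, L = L)
      s <- s + sum(occ$occupancy)
    }
    s / total_bases - target
  }
  uniroot(f, interval = interval, tol = 1e-4)$root
}
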