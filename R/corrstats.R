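#' Base-by-base correlation between two genome tracks
#'
#' Computed over jointly defined bases only. Spearman uses average ranks for
#' ties. The p-value comes from the standard t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and is
#' clipped below at the smallest positive double (so a vanishing p is
#' reported as `2.2e-308`-scale rather than 0).
#'
#' @param x,y `GenomeTrack`s sharing a chromosome namespace.
#' @param method `"pearson"` or `"spearman"`.
#' @return a `CorrelationResult`: list with `r`, `p`, `n`, `method`.
#' @export
correlate_tracks <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  jd <- joint_defined(x, y)
  xv <- unlist(lapply(names(jd), function(ch) x$values[[ch]][jd[[ch]]]),
               use.names = FALSE)
  yv <- unlist(lapply(names(jd), function(ch) y$values[[ch]][jd[[ch]]]),
               use.names = FALSE)
  correlate_values(xv, yv, method)
}

#' Correlation between paired value vectors
#'
#' Workhorse behind [correlate_tracks()] and [correlate_at_positions()].
#'
#' @param xv,yv numeric vectors of equal length >= 2, no `NA`.
#' @param method `"pearson"` or `"spearman"`.
#' @return a `CorrelationResult`.
#' @export
correlate_values <- function(xv, yv, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(xv) != length(yv)) stop("x and y must have equal length")
  n <- length(xv)
  if (n < 2L) stop("need at least 2 jointly defined bases")
  if (method == "spearman") {
    xv <- data.table::frank(xv, ties.method = "average")
    yv <- data.table::frank(yv, ties.method = "average")
  }
  r <- stats::cor(xv, yv)
  if (is.na(r)) stop("correlation undefined (zero variance input)")
  p <- if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  p <- max(p, .Machine$double.xmin)
  structure(list(r = r, p = p, n = n, method = method),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("CorrelationResult (%s): r = %.4f, p = %.3g, n = %d\n",
              x$method, x$r, x$p, x$n))
  invisible(x)
}

#' Subsampling specification for spacing-constrained position draws
#'
#' @param n_per_chrom positions drawn per chromosome (default 1000).
#' @param min_dist minimum pairwise distance within a chromosome, in bases
#'   (default 150).
#' @param seed RNG seed (per-chromosome streams are derived from it).
#' @export
subsample_spec <- function(n_per_chrom = 1000L, min_dist = 150L, seed = 1L) {
  if (n_per_chrom < 1L) stop("n_per_chrom must be >= 1")
  if (min_dist < 0L) stop("min_dist must be >= 0")
  structure(list(n_per_chrom = as.integer(n_per_chrom),
                 min_dist = as.integer(min_dist), seed = as.integer(seed)),
            class = "SubsampleSpec")
}

#' Draw spaced positions where two tracks are jointly defined
#'
#' Draws exactly `n_per_chrom` jointly defined positions per chromosome with
#' all within-chromosome pairwise distances >= `min_dist`, reproducibly for
#' a given seed. Sampling is by rejection with a retry cap; if the cap is
#' hit, a deterministic greedy fill completes the draw and the result is
#' flagged (`attr(, "greedy_fallback")`). Infeasible chromosomes (maximum
#' packing of eligible bases below `n_per_chrom`) raise an error naming the
#' chromosome.
#'
#' @param x,y `GenomeTrack`s defining eligibility (jointly defined bases).
#' @param spec a [subsample_spec()].
#' @return data frame with columns `chrom`, `pos` (1-based).
#' @export
subsample_positions <- function(x, y, spec) {
  stopifnot(inherits(spec, "SubsampleSpec"))
  jd <- joint_defined(x, y)
  out <- list()
  any_greedy <- FALSE
  for (ch in names(jd)) {
    eligible <- jd[[ch]]
    packing <- .max_packing(eligible, spec$min_dist)
    if (packing < spec$n_per_chrom) {
      stop(sprintf("chromosome %s cannot host %d positions %d bases apart (max %d)",
                   ch, spec$n_per_chrom, spec$min_dist, packing))
    }
    set.seed(derive_seed(spec$seed, ch))
    res <- .rejection_sample(eligible, spec$n_per_chrom, spec$min_dist,
                             n_bases = length(x$values[[ch]]))
    any_greedy <- any_greedy || res$greedy
    out[[ch]] <- data.frame(chrom = ch, pos = sort(res$positions))
  }
  df <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(df, "greedy_fallback") <- any_greedy
  df
}

# maximum number of eligible (sorted) positions with pairwise distance >= d:
# greedy left-to-right is optimal for interval packing
.max_packing <- function(eligible, d) {
  k <- 0L
  last <- -Inf
  for (p in eligible) {
    if (p - last >= d) { k <- k + 1L; last <- p }
  }
  k
}

.rejection_sample <- function(eligible, n_target, d, n_bases) {
  blocked <- rep(FALSE, n_bases)
  taken <- integer(0)
  cap <- 200L * n_target
  attempts <- 0L
  while (length(taken) < n_target && attempts < cap) {
    attempts <- attempts + 1L
    p <- eligible[sample.int(length(eligible), 1L)]
    if (blocked[p]) next
    taken <- c(taken, p)
    if (d > 0L) blocked[max(1L, p - d + 1L):min(n_bases, p + d - 1L)] <- TRUE
  }
  greedy <- FALSE
  if (length(taken) < n_target) {
    # deterministic greedy fill over a randomly rotated scan of the eligible
    # positions; guaranteed to terminate
    greedy <- TRUE
    message("subsample rejection stalled; completing with greedy fill")
    start <- sample.int(length(eligible), 1L)
    scan <- eligible[c(start:length(eligible), seq_len(start - 1L))]
    for (p in scan) {
      if (length(taken) >= n_target) break
      if (!blocked[p]) {
        taken <- c(taken, p)
        if (d > 0L) blocked[max(1L, p - d + 1L):min(n_bases, p + d - 1L)] <- TRUE
      }
    }
    if (length(taken) < n_target) {
      # the random blocking may have painted us into a corner: restart from
      # scratch with the optimal deterministic packing
      taken <- integer(0)
      last <- -Inf
      for (p in eligible) {
        if (length(taken) >= n_target) break
        if (p - last >= d) { taken <- c(taken, p); last <- p }
      }
    }
  }
  list(positions = taken, greedy = greedy)
}

#' Correlation restricted to sampled positions
#'
#' @param x,y `GenomeTrack`s.
#' @param positions data frame with `chrom` and `pos` (1-based), as returned
#'   by [subsample_positions()]; all positions must be jointly defined.
#' @param method `"pearson"` or `"spearman"`.
#' @return a `CorrelationResult`.
#' @export
correlate_at_positions <- function(x, y, positions,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xv <- numeric(0); yv <- numeric(0)
  for (ch in unique(positions$chrom)) {
    p <- positions$pos[positions$chrom == ch]
    vx <- x$values[[ch]][p]; vy <- y$values[[ch]][p]
    if (anyNA(vx) || anyNA(vy)) stop("positions must be jointly defined (", ch, ")")
    xv <- c(xv, vx); yv <- c(yv, vy)
  }
  correlate_values(xv, yv, method)
}

#' Quadrant fractions of the joint (x, y) base distribution
#'
#' Every jointly defined base is assigned to one of four quadrants by sign
#' relative to `(x_split, y_split)`; values exactly at a split go to the
#' lower/left side. With `box_limits`, each named quadrant is instead a
#' finite box `c(xmin, xmax, ymin, ymax)` (half-open on the upper edges) and
#' fractions are still of all jointly defined bases, so boxed fractions need
#' not sum to 1.
#'
#' @param x,y `GenomeTrack`s (normalized tracks make 0/0 the genomic mean).
#' @param x_split,y_split quadrant thresholds (default 0).
#' @param box_limits optional named list of boxes for
#'   `upper_left`, `upper_right`, `lower_left`, `lower_right`.
#' @return a `QuadrantResult`: list with `fractions` (named), `thresholds`,
#'   `n`.
#' @export
quadrant_fractions <- function(x, y, x_split = 0, y_split = 0,
                               box_limits = NULL) {
  jd <- joint_defined(x, y)
  xv <- unlist(lapply(names(jd), function(ch) x$values[[ch]][jd[[ch]]]),
               use.names = FALSE)
  yv <- unlist(lapply(names(jd), function(ch) y$values[[ch]][jd[[ch]]]),
               use.names = FALSE)
  n <- length(xv)
  if (n < 1L) stop("no jointly defined bases")
  qnames <- c("upper_left", "upper_right", "lower_left", "lower_right")
  if (is.null(box_limits)) {
    right <- xv > x_split
    upper <- yv > y_split
    fractions <- c(
      upper_left  = sum(!right & upper) / n,
      upper_right = sum(right & upper) / n,
      lower_left  = sum(!right & !upper) / n,
      lower_right = sum(right & !upper) / n
    )
  } else {
    stopifnot(all(names(box_limits) %in% qnames))
    fractions <- vapply(box_limits, function(b) {
      sum(xv >= b[1] & xv < b[2] & yv >= b[3] & yv < b[4]) / n
    }, numeric(1))
  }
  structure(list(fractions = fractions,
                 thresholds = c(x_split = x_split, y_split = y_split),
                 n = n),
            class = "QuadrantResult")
}

#' @export
print.QuadrantResult <- function(x, ...) {
  cat("QuadrantResult over", x$n, "bases:\n")
  print(round(x$fractions, 4))
  invisible(x)
}
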