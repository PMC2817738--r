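#' Strand-aware meta-profile of a track around anchors
#'
#' For each anchor, relative offset `o` maps to genomic base `anchor + o` on
#' the plus (or unstranded) orientation and `anchor - o` on the minus strand,
#' so upstream is always to the left. The anchor base is the TSS for
#' `anchor_mode = "tss"` (requires stranded anchors) and
#' `floor((start + end) / 2)` of the 0-based half-open interval for
#' `"center"`. Undefined bases and offsets falling off a chromosome simply do
#' not contribute; `support` counts contributing anchors per offset.
#'
#' @param track a `GenomeTrack`.
#' @param anchors a `GRanges` of anchor intervals.
#' @param flank profile half-width in bases (offsets `-flank..flank`).
#' @param anchor_mode `"center"` or `"tss"`.
#' @return a `MetaProfile`: data frame with columns `offset`, `mean`
#'   (`NA` where support is 0) and `support`.
#' @export
meta_profile <- function(track, anchors, flank = 1000,
                         anchor_mode = c("center", "tss")) {
  stopifnot(inherits(track, "GenomeTrack"), methods::is(anchors, "GRanges"))
  anchor_mode <- match.arg(anchor_mode)
  if (length(anchors) == 0L) stop("empty anchor set")
  if (flank < 0) stop("flank must be >= 0")
  strand <- as.character(GenomicRanges::strand(anchors))
  if (anchor_mode == "tss" && any(strand == "*")) {
    stop("anchor_mode = 'tss' requires stranded anchors")
  }
  pos <- if (anchor_mode == "tss") {
    ifelse(strand == "+", GenomicRanges::start(anchors),
           GenomicRanges::end(anchors))
  } else {
    # midpoint of the 0-based half-open interval, back in 1-based indexing
    floor((GenomicRanges::start(anchors) - 1L + GenomicRanges::end(anchors)) / 2) + 1L
  }
  sgn <- ifelse(strand == "-", -1L, 1L)
  off <- (-flank):flank
  K <- length(off)
  total <- numeric(K)
  support <- integer(K)
  chs <- as.character(GenomeInfoDb::seqnames(anchors))
  for (ch in unique(chs)) {
    v <- track$values[[ch]]
    if (is.null(v)) stop("anchor chromosome absent from track: ", ch)
    sel <- chs == ch
    idx <- matrix(pos[sel], nrow = sum(sel), ncol = K) + outer(sgn[sel], off)
    idx[idx < 1L | idx > length(v)] <- NA_integer_
    vals <- matrix(v[idx], nrow = sum(sel), ncol = K)
    total <- total + colSums(vals, na.rm = TRUE)
    support <- support + colSums(!is.na(vals))
  }
  mean <- ifelse(support > 0L, total / support, NA_real_)
  structure(data.frame(offset = off, mean = mean, support = support),
            class = c("MetaProfile", "data.frame"),
            flank = flank, anchor_mode = anchor_mode)
}

#' Write a meta-profile as tab-separated text
#' @param profile a `MetaProfile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Windowed sequence statistics (G+C fraction, AAAA frequency)
#'
#' The value at 0-based position `i` is a statistic of the 150-base window
#' \[i-75, i+75): the window is even-width, so registration is left-heavy
#' (the value sits at offset +75 of its window). `gc` is the G+C fraction of
#' the window; `aaaa` is the number of (overlapping) AAAA occurrences among
#' the window's `width - 3` start positions, divided by `width - 3`. Windows
#' containing N, or running off the sequence, are undefined.
#'
#' @param sequence a DNA string.
#' @param stat `"gc"` or `"aaaa"`.
#' @param width window width in bases (default 150; >= 4 for `"aaaa"`).
#' @return numeric vector of per-base values in \[0, 1\] (`NA` = undefined).
#' @export
window_stat <- function(sequence, stat = c("gc", "aaaa"), width = 150L) {
  stat <- match.arg(stat)
  width <- as.integer(width)
  if (stat == "aaaa" && width < 4L) stop("width must be >= 4 for the AAAA statistic")
  if (width < 1L) stop("width must be >= 1")
  codes <- seq_to_codes(sequence)
  n <- length(codes)
  out <- rep(NA_real_, n)
  if (n < width) return(out)
  half <- width %/% 2L
  # window for value position j (1-based) spans [j - half, j + width - half - 1]
  js <- (half + 1L):(n - (width - half) + 1L)
  ws <- js - half  # window start, length n - width + 1 values
  win_sum <- function(x, w) {
    cs <- c(0, cumsum(x))
    cs[ws + w] - cs[ws]
  }
  n_amb <- win_sum(is.na(codes), width)
  val <- if (stat == "gc") {
    win_sum(!is.na(codes) & (codes == 2L | codes == 3L), width) / width
  } else {
    a <- !is.na(codes) & codes == 1L
    quad <- a[1:(n - 3L)] & a[2:(n - 2L)] & a[3:(n - 1L)] & a[4:n]
    win_sum(c(quad, rep(FALSE, 3L)), width - 3L) / (width - 3L)
  }
  val[n_amb > 0] <- NA_real_
  out[js] <- val
  out
}

#' Windowed sequence statistic as a genome track
#'
#' Applies [window_stat()] per chromosome.
#'
#' @inheritParams window_stat
#' @param genome a `DNAStringSet` or named character vector.
#' @return a `GenomeTrack` with attributes `stat` and `width`.
#' @export
window_stat_track <- function(genome, stat = c("gc", "aaaa"), width = 150L) {
  stat <- match.arg(stat)
  seqs <- as_genome_seqs(genome)
  tr <- genome_track(lapply(seqs, window_stat, stat = stat, width = width))
  attr(tr, "stat") <- stat
  attr(tr, "width") <- width
  tr
}
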