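#' Per-base genome track
#'
#' The universal currency of the pipeline: one numeric vector per chromosome,
#' with `NA` marking undefined bases. Coordinates are 0-based half-open at
#' every file boundary; in memory, R's 1-based indexing applies (base `i` of
#' the vector is genomic position `i - 1`).
#'
#' @param values named list of numeric vectors (`NA` = undefined).
#' @return an object of class `GenomeTrack`.
#' @export
genome_track <- function(values) {
  if (!is.list(values) || length(values) == 0L) {
    stop("`values` must be a nonempty named list of numeric vectors")
  }
  nm <- names(values)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("chromosome names must be present and unique")
  }
  values <- lapply(values, as.numeric)
  for (ch in nm) {
    v <- values[[ch]]
    if (any(!is.finite(v) & !is.na(v))) {
      stop("non-finite defined value on ", ch)
    }
  }
  structure(list(values = values), class = "GenomeTrack")
}

#' @export
print.GenomeTrack <- function(x, ...) {
  s <- track_summary(x)
  cat(sprintf("GenomeTrack: %d chromosome(s), %d defined bases, mean %.6g\n",
              s$chromosomes, s$defined_bases, s$genomic_mean))
  invisible(x)
}

#' Chromosome lengths of a track
#' @param track a `GenomeTrack`.
#' @export
track_lengths <- function(track) {
  vapply(track$values, length, numeric(1))
}

#' Summarize a track over its defined bases
#'
#' @param track a `GenomeTrack`.
#' @return a `TrackSummary`: `genomic_mean` (over defined bases only),
#'   `defined_bases`, `chromosomes`.
#' @export
track_summary <- function(track) {
  stopifnot(inherits(track, "GenomeTrack"))
  v <- unlist(track$values, use.names = FALSE)
  structure(list(genomic_mean = mean(v, na.rm = TRUE),
                 defined_bases = sum(!is.na(v)),
                 chromosomes = length(track$values)),
            class = "TrackSummary")
}

#' @export
print.TrackSummary <- function(x, ...) {
  cat(sprintf("TrackSummary: mean %.6g over %d defined bases on %d chromosome(s)\n",
              x$genomic_mean, x$defined_bases, x$chromosomes))
  invisible(x)
}

#' Normalize a track to log2 ratio over the genomic mean, centred at zero
#'
#' Each defined base becomes `log2(x / genomic_mean)`; the result is then
#' mean-centred over defined bases so the genomic average is exactly zero.
#' The mean is global across chromosomes, not per-chromosome. Masks are
#' preserved.
#'
#' @param track a `GenomeTrack` with strictly positive defined values (floor
#'   count-like tracks with [floor_track()] first).
#' @return a `GenomeTrack` whose defined-base mean is < 1e-12 in magnitude.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "GenomeTrack"))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop(sprintf("non-positive defined value %g at %s:%d (0-based); floor the track first",
                   v[bad[1L]], ch, bad[1L] - 1L))
    }
  }
  all_v <- unlist(track$values, use.names = FALSE)
  if (all(is.na(all_v))) stop("track has no defined bases")
  gm <- mean(all_v, na.rm = TRUE)
  logged <- lapply(track$values, function(v) log2(v / gm))
  m <- mean(unlist(logged, use.names = FALSE), na.rm = TRUE)
  genome_track(lapply(logged, function(v) v - m))
}

#' Floor a count-like track before log transformation
#'
#' Real MNase coverage contains zero-read bases; the log2 normalization
#' requires strictly positive input. The default floor is half the smallest
#' positive defined value, preserving rank order; the floor used is reported
#' via `message()` and attached as attribute `floor`.
#'
#' @param track a `GenomeTrack` with nonnegative defined values.
#' @param floor positive pseudo-floor; `NULL` for the default.
#' @return the floored `GenomeTrack`.
#' @export
floor_track <- function(track, floor = NULL) {
  stopifnot(inherits(track, "GenomeTrack"))
  v <- unlist(track$values, use.names = FALSE)
  if (is.null(floor)) {
    pos <- v[!is.na(v) & v > 0]
    if (length(pos) == 0L) stop("track has no positive defined values")
    floor <- min(pos) / 2
  }
  if (!is.finite(floor) || floor <= 0) stop("floor must be a positive number")
  message(sprintf("flooring track at %g", floor))
  out <- genome_track(lapply(track$values, function(x) pmax(x, floor)))
  attr(out, "floor") <- floor
  out
}

# positions (1-based, per chromosome) where both tracks are defined
joint_defined <- function(x, y) {
  stopifnot(inherits(x, "GenomeTrack"), inherits(y, "GenomeTrack"))
  chroms <- intersect(names(x$values), names(y$values))
  if (length(chroms) == 0L) stop("tracks share no chromosomes")
  lapply(stats::setNames(chroms, chroms), function(ch) {
    vx <- x$values[[ch]]; vy <- y$values[[ch]]
    if (length(vx) != length(vy)) {
      stop("chromosome ", ch, " has different lengths in the two tracks")
    }
    which(!is.na(vx) & !is.na(vy))
  })
}

#' Read a per-base track from bedGraph or wiggle
#'
#' Accepts bedGraph and fixedStep/variableStep wiggle (span supported) via
#' `rtracklayer`. Bases covered by no record are undefined; overlapping
#' records are ambiguous and raise an error; records outside
#' `genome_lengths`, or on chromosomes absent from it, raise an error.
#'
#' @param path input file (`.bedGraph`/`.bg`/`.wig`).
#' @param genome_lengths named vector of chromosome lengths; every named
#'   chromosome appears in the output (all-`NA` when absent from the file).
#' @return a `GenomeTrack`.
#' @export
load_track <- function(path, genome_lengths) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(names(genome_lengths))) stop("genome_lengths must be named")
  fmt <- .track_format(path)
  if (fmt == "bedGraph") .validate_bedgraph_lines(path)
  gr <- tryCatch(
    rtracklayer::import(path, format = fmt),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  values <- lapply(stats::setNames(names(genome_lengths), names(genome_lengths)),
                   function(ch) rep(NA_real_, genome_lengths[[ch]]))
  if (length(gr)) {
    chs <- as.character(GenomeInfoDb::seqnames(gr))
    unknown <- setdiff(unique(chs), names(genome_lengths))
    if (length(unknown)) {
      stop("unknown chromosome(s) in ", path, ": ", paste(unknown, collapse = ", "))
    }
    for (ch in unique(chs)) {
      sel <- chs == ch
      st <- GenomicRanges::start(gr)[sel]; en <- GenomicRanges::end(gr)[sel]
      if (any(st < 1L) || any(en > genome_lengths[[ch]])) {
        stop("record outside chromosome bounds on ", ch)
      }
      sc <- gr$score[sel]
      o <- order(st)
      st <- st[o]; en <- en[o]; sc <- sc[o]
      if (length(st) > 1L && any(st[-1L] <= en[-length(en)])) {
        stop("overlapping records on ", ch, " (ambiguous)")
      }
      v <- values[[ch]]
      w <- en - st + 1L
      v[sequence(w, from = st)] <- rep(sc, w)
      values[[ch]] <- v
    }
  }
  genome_track(values)
}

.track_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         "bedgraph" = "bedGraph", "bg" = "bedGraph",
         "wig" = "wig", "wiggle" = "wig",
         stop("cannot infer track format from extension: ", path))
}

# cheap pre-scan so malformed bedGraph lines are reported with a line number
.validate_bedgraph_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "track") || startsWith(ln, "#")) next
    f <- strsplit(ln, "[ \t]+")[[1L]]
    if (length(f) < 4L || anyNA(suppressWarnings(as.numeric(f[2:4])))) {
      stop(sprintf("malformed bedGraph line %d in %s: %s", i, path, ln))
    }
  }
  invisible(TRUE)
}

#' Write a track as run-length-collapsed bedGraph
#'
#' Runs of equal defined values collapse to single records (0-based
#' half-open); undefined runs are omitted. Values are printed with 9
#' significant digits so a save/load roundtrip preserves them to well within
#' 1e-6 relative error.
#'
#' @param track a `GenomeTrack`.
#' @param path output path (conventionally `.bedGraph`).
#' @export
save_track <- function(track, path) {
  stopifnot(inherits(track, "GenomeTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (length(v) == 0L) next
    r <- rle(ifelse(is.na(v), "NA", sprintf("%.9g", v)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    keep <- r$values != "NA"
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' Read a two-column chromosome-length table
#' @param path tab- or space-separated file: chromosome, length.
#' @return named numeric vector.
#' @export
read_chrom_lengths <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$length, df$chrom)
}
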