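#' Proximal promoter windows around transcription start sites
#'
#' The window \[-`upstream`, 0\] relative to the TSS, endpoints inclusive, so
#' the default `upstream = 150` yields 151-base intervals: a plus-strand TSS
#' at 0-based position t maps to \[t-150, t+1) and a minus-strand TSS to
#' \[t, t+151), clipped to chromosome bounds.
#'
#' @param tss a stranded `GRanges` of width-1 TSS positions (strand + or -).
#' @param upstream bases upstream of the TSS included (default 150).
#' @param chrom_lengths optional named vector used to clip windows.
#' @return a `GRanges` of promoter windows.
#' @export
make_proximal_promoters <- function(tss, upstream = 150, chrom_lengths = NULL) {
  stopifnot(methods::is(tss, "GRanges"))
  if (any(GenomicRanges::strand(tss) == "*")) {
    stop("TSS must be stranded (+ or -)")
  }
  prom <- GenomicRanges::promoters(tss, upstream = upstream, downstream = 1)
  # clip to [1, chromosome length]
  GenomicRanges::start(prom) <- pmax(GenomicRanges::start(prom), 1L)
  if (!is.null(chrom_lengths)) {
    chs <- as.character(GenomeInfoDb::seqnames(prom))
    lim <- unname(chrom_lengths[chs])
    if (anyNA(lim)) stop("chromosome missing from chrom_lengths")
    GenomicRanges::end(prom) <- pmin(GenomicRanges::end(prom), as.integer(lim))
  }
  prom
}

#' Classify promoters as CpG or non-CpG by island overlap
#'
#' A promoter is `CpG` iff it shares at least one base with any island;
#' half-open adjacency is not overlap. The two classes partition the set.
#'
#' @param promoters a `GRanges` of promoter windows.
#' @param islands a `GRanges` of CpG islands (may be empty).
#' @return `promoters` with a metadata column `cpg_class` of
#'   `"CpG"`/`"non-CpG"`.
#' @export
classify_promoters_cpg <- function(promoters, islands) {
  stopifnot(methods::is(promoters, "GRanges"), methods::is(islands, "GRanges"))
  hit <- IRanges::overlapsAny(promoters, islands, ignore.strand = TRUE)
  promoters$cpg_class <- ifelse(hit, "CpG", "non-CpG")
  promoters
}

#' Call CpG islands on sequence
#'
#' Classic criteria: maximal regions of length >= `min_length` with G+C
#' fraction >= `min_gc` and observed/expected CpG >= `min_oe`, where expected
#' CpG = (#C * #G) / length (at least one observed CpG is required, so the
#' ratio is well defined). The caller seeds on `min_length`-base windows that
#' pass all criteria, merges nearby seeds, and inside each seeded
#' neighbourhood emits disjoint islands by a leftmost-start, longest-extent
#' greedy over all criteria-passing intervals; sequences up to 5 kb skip
#' seeding and get the exact global greedy. A passing interval containing no
#' passing seed window is not called on longer sequences (the standard
#' seeding assumption). N bases count against every criterion.
#'
#' @param sequence a DNA string, or a named set of them
#'   (`DNAStringSet`/character vector) for per-chromosome calling.
#' @param chrom chromosome name used when `sequence` is a single string.
#' @param min_length,min_gc,min_oe island criteria (defaults 200, 0.5, 0.6).
#' @return a `GRanges` of disjoint islands.
#' @export
call_cpg_islands <- function(sequence, chrom = "chr",
                             min_length = 200L, min_gc = 0.5, min_oe = 0.6) {
  if (methods::is(sequence, "DNAStringSet") ||
      (is.character(sequence) && length(sequence) > 1L) ||
      (is.character(sequence) && !is.null(names(sequence)))) {
    seqs <- as_genome_seqs(sequence)
    grl <- lapply(names(seqs), function(ch) {
      call_cpg_islands(seqs[[ch]], chrom = ch, min_length = min_length,
                       min_gc = min_gc, min_oe = min_oe)
    })
    return(suppressWarnings(do.call(c, grl)))
  }
  iv <- .cpg_islands_core(seq_to_codes(sequence), min_length, min_gc, min_oe)
  if (nrow(iv) == 0L) {
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges()))
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(iv$start, iv$end))
}

# prefix-sum island machinery; coordinates 1-based inclusive internally
.cpg_islands_core <- function(codes, min_length, min_gc, min_oe) {
  n <- length(codes)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < min_length) return(empty)
  isC <- !is.na(codes) & codes == 2L
  isG <- !is.na(codes) & codes == 3L
  cpg <- isC & c(isG[-1L], FALSE)         # CpG start positions
  cC <- c(0, cumsum(isC))
  cG <- c(0, cumsum(isG))
  cGC <- c(0, cumsum(isC | isG))
  cP <- c(0, cumsum(cpg))
  # pass(s, e) for vectors s, e (1-based inclusive); CpG starts counted in
  # [s, e-1] so the dinucleotide lies fully inside
  pass <- function(s, e) {
    len <- e - s + 1
    nC <- cC[e + 1] - cC[s]
    nG <- cG[e + 1] - cG[s]
    gc <- cGC[e + 1] - cGC[s]
    np <- cP[e] - cP[s]
    len >= min_length & gc >= min_gc * len & np >= 1 & np * len >= min_oe * nC * nG
  }
  # short sequences: exact global greedy, no seeding
  if (n <= 5000L) return(.greedy_islands(pass, 1L, n, min_length))
  # seeds: min_length windows passing all criteria
  ws <- seq_len(n - min_length + 1L)
  seed <- pass(ws, ws + min_length - 1L)
  if (!any(seed)) return(empty)
  sr <- IRanges::reduce(IRanges::IRanges(ws[seed], ws[seed] + min_length - 1L),
                        min.gapwidth = min_length)
  # seeded neighbourhoods, expanded and re-merged so they are well separated
  nb <- IRanges::reduce(IRanges::IRanges(
    pmax(1L, IRanges::start(sr) - min_length),
    pmin(n, IRanges::end(sr) + min_length)))
  out <- list()
  for (k in seq_len(length(nb))) {
    a <- IRanges::start(nb)[k]
    b <- IRanges::end(nb)[k]
    repeat {
      iv <- .greedy_islands(pass, a, b, min_length)
      grew <- FALSE
      if (nrow(iv)) {
        # adaptive widening when an island abuts the search bounds
        if (iv$start[1L] == a && a > 1L) { a <- max(1L, a - min_length); grew <- TRUE }
        if (iv$end[nrow(iv)] == b && b < n) { b <- min(n, b + min_length); grew <- TRUE }
      }
      if (!grew) break
    }
    out[[length(out) + 1L]] <- iv
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$start), , drop = FALSE]
  # adaptive widening can, in principle, make neighbourhoods collide; if two
  # islands overlap, redo the greedy over their joint hull
  while (nrow(res) > 1L && any(res$start[-1L] <= res$end[-nrow(res)])) {
    k <- which(res$start[-1L] <= res$end[-nrow(res)])[1L]
    a <- max(1L, min(res$start[k], res$start[k + 1L]) - min_length)
    b <- min(n, max(res$end[k], res$end[k + 1L]) + min_length)
    redo <- .greedy_islands(pass, a, b, min_length)
    res <- unique(rbind(res[-c(k, k + 1L), , drop = FALSE], redo))
    res <- res[order(res$start), , drop = FALSE]
  }
  res
}

# leftmost-start then longest-extent greedy over passing intervals in [a, b]
.greedy_islands <- function(pass, a, b, min_length) {
  out_s <- integer(0); out_e <- integer(0)
  s <- a
  while (s + min_length - 1L <= b) {
    es <- (s + min_length - 1L):b
    ok <- pass(rep.int(s, length(es)), es)
    if (any(ok)) {
      e <- es[max(which(ok))]
      out_s <- c(out_s, s); out_e <- c(out_e, e)
      s <- e + 1L
    } else {
      s <- s + 1L
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Drop regions overlapping promoter windows
#'
#' Removes any region sharing at least one base with a \[-`upstream`, 0\]
#' window of a TSS (built as in [make_proximal_promoters()]).
#'
#' @param regions a `GRanges`.
#' @param tss stranded width-1 `GRanges` of TSS positions.
#' @param upstream promoter window size (default 1000).
#' @param chrom_lengths optional clipping bounds.
#' @return the non-promoter subset of `regions`.
#' @export
filter_nonpromoter <- function(regions, tss, upstream = 1000, chrom_lengths = NULL) {
  stopifnot(methods::is(regions, "GRanges"))
  if (length(tss) == 0L) return(regions)
  win <- make_proximal_promoters(tss, upstream = upstream,
                                 chrom_lengths = chrom_lengths)
  regions[!IRanges::overlapsAny(regions, win, ignore.strand = TRUE)]
}

#' Restrict items to designated study regions by midpoint
#'
#' An item is kept iff its midpoint (0-based `floor((start + end) / 2)` of
#' the half-open interval) lies inside a study region; midpoint containment
#' avoids double-keeping straddlers.
#'
#' @param items a `GRanges`.
#' @param study_regions a `GRanges` (empty set yields empty output).
#' @return the retained subset of `items`.
#' @export
restrict_to_regions <- function(items, study_regions) {
  stopifnot(methods::is(items, "GRanges"), methods::is(study_regions, "GRanges"))
  if (length(items) == 0L || length(study_regions) == 0L) return(items[integer(0)])
  mid0 <- floor((GenomicRanges::start(items) - 1L + GenomicRanges::end(items)) / 2)
  pts <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(items),
                                IRanges::IRanges(mid0 + 1L, width = 1L))
  items[IRanges::overlapsAny(pts, study_regions, ignore.strand = TRUE)]
}

#' Read / write BED6 interval files
#'
#' Tab-separated BED6 (0-based half-open on disk, strand in column 6) via
#' `rtracklayer`; TSS files are BED6 of 1-base intervals.
#'
#' @param path file path.
#' @rdname bed_io
#' @return `read_bed`: a `GRanges`.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' @param gr a `GRanges` to write.
#' @rdname bed_io
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
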