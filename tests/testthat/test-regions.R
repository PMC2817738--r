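gr <- function(chrom, start0, end0, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0), strand = strand)
}

test_that("proximal promoter windows are 151 bases, strand-aware, clipped", {
  tss <- gr("chr1", c(1000, 1000, 50), c(1001, 1001, 51),
            strand = c("+", "-", "+"))
  prom <- make_proximal_promoters(tss, upstream = 150,
                                  chrom_lengths = c(chr1 = 5000))
  # + strand TSS at 0-based 1000 -> [850, 1001)
  expect_equal(GenomicRanges::start(prom)[1] - 1, 850)
  expect_equal(GenomicRanges::end(prom)[1], 1001)
  # - strand TSS at 0-based 1000 -> [1000, 1151)
  expect_equal(GenomicRanges::start(prom)[2] - 1, 1000)
  expect_equal(GenomicRanges::end(prom)[2], 1151)
  # clipping at the chromosome start: [0, 51)
  expect_equal(GenomicRanges::start(prom)[3] - 1, 0)
  expect_equal(GenomicRanges::end(prom)[3], 51)
  expect_equal(GenomicRanges::width(prom), c(151, 151, 51))
  expect_error(make_proximal_promoters(gr("chr1", 10, 11, "*")), "strand")
})

test_that("CpG classification follows >=1 shared base with half-open adjacency", {
  prom <- gr("chr1", c(850, 850), c(1001, 1001), strand = c("+", "+"))
  expect_equal(classify_promoters_cpg(prom, gr("chr1", 900, 920))$cpg_class,
               c("CpG", "CpG"))
  # island starting exactly at the promoter end does not overlap
  expect_equal(classify_promoters_cpg(prom, gr("chr1", 1001, 1100))$cpg_class,
               c("non-CpG", "non-CpG"))
  empty <- GenomicRanges::GRanges()
  expect_equal(classify_promoters_cpg(prom, empty)$cpg_class,
               c("non-CpG", "non-CpG"))
})

test_that("classification is invariant to island order and splitting", {
  prom <- gr("chr1", c(0, 300, 600), c(151, 451, 751), strand = rep("+", 3))
  isl <- gr("chr1", c(100, 650), c(200, 700))
  isl_rev <- rev(isl)
  isl_split <- gr("chr1", c(100, 150, 650), c(150, 200, 700))
  c1 <- classify_promoters_cpg(prom, isl)$cpg_class
  expect_equal(classify_promoters_cpg(prom, isl_rev)$cpg_class, c1)
  expect_equal(classify_promoters_cpg(prom, isl_split)$cpg_class, c1)
})

test_that("CpG island caller handles the canonical constructed cases", {
  # 500 bp poly-A: nothing
  expect_length(call_cpg_islands(strrep("A", 500)), 0)
  # (CG) x 100 in poly-A: GC = 1, obs = 100, expected = 50 over the repeat;
  # exactly one island, containing the whole repeat, and itself passing all
  # criteria while neither one-base extension does
  s <- paste0(strrep("A", 300), strrep("CG", 100), strrep("A", 300))
  isl <- call_cpg_islands(s)
  expect_length(isl, 1)
  expect_lte(GenomicRanges::start(isl), 301)
  expect_gte(GenomicRanges::end(isl), 500)
  expect_equal(cbind(GenomicRanges::start(isl), GenomicRanges::end(isl)),
               brute_cpg_islands(s), ignore_attr = TRUE)
  # a repeat shorter than 200 bases with no flanking sequence to borrow
  # fails the length criterion outright
  expect_length(call_cpg_islands(substr(strrep("CG", 100), 1, 199)), 0)
})

test_that("island caller agrees exactly with the brute-force maximal search", {
  set.seed(29)
  n_agree <- 0
  for (rep in 1:100) {
    # constructed sequences: AT-rich background with 0-3 embedded GC/CpG-rich
    # blocks of varying strength and length
    n <- sample(300:2000, 1)
    s <- strsplit(random_dna(n, gc = 0.36), "")[[1]]
    for (b in seq_len(sample(0:3, 1))) {
      len <- sample(150:min(600, n - 160), 1)
      at <- sample(n - len, 1)
      gc <- runif(1, 0.45, 0.8)
      block <- strsplit(random_dna(len, gc = gc), "")[[1]]
      # enrich CpGs by pasting CG dimers at random spots
      k <- rbinom(1, len %/% 2, runif(1, 0.1, 0.5))
      if (k > 0) {
        pos <- sample(len - 1, k)
        block[pos] <- "C"; block[pos + 1] <- "G"
      }
      s[at:(at + len - 1)] <- block
    }
    s <- paste(s, collapse = "")
    called <- call_cpg_islands(s)
    expected <- brute_cpg_islands(s)
    if (is.null(expected)) {
      expect_length(called, 0)
    } else {
      expect_equal(GenomicRanges::start(called), expected[, 1])
      expect_equal(GenomicRanges::end(called), expected[, 2])
    }
    n_agree <- n_agree + 1
  }
  expect_equal(n_agree, 100)
})

test_that("called islands are disjoint, criteria-passing and maximal", {
  passes <- function(s, from, to) {
    w <- strsplit(substr(s, from, to), "")[[1]]
    len <- length(w)
    nC <- sum(w == "C"); nG <- sum(w == "G")
    np <- sum(w[-len] == "C" & w[-1] == "G")
    len >= 200 && (nC + nG) >= 0.5 * len && np >= 1 && np * len >= 0.6 * nC * nG
  }
  set.seed(31)
  for (rep in 1:10) {
    s <- paste0(random_dna(400, 0.3), strrep("CG", sample(100:200, 1)),
                random_dna(300, 0.35), random_dna(400, gc = 0.75))
    isl <- call_cpg_islands(s)
    if (length(isl) == 0) next
    st <- GenomicRanges::start(isl); en <- GenomicRanges::end(isl)
    if (length(isl) > 1) expect_true(all(st[-1] > en[-length(en)]))
    for (k in seq_along(st)) {
      expect_true(passes(s, st[k], en[k]))
      # one-base extension fails a criterion, hits the sequence boundary, or
      # runs into a neighbouring island
      if (st[k] > 1 && !(st[k] - 1) %in% en) {
        expect_false(passes(s, st[k] - 1, en[k]))
      }
      if (en[k] < nchar(s) && !(en[k] + 1) %in% st) {
        expect_false(passes(s, st[k], en[k] + 1))
      }
    }
  }
})

test_that("non-promoter filtering removes [-1000, 0] overlaps with clipping", {
  tss <- gr("chr1", 500, 501, "+")
  regions <- gr("chr1", c(0, 600), c(100, 700))
  kept <- filter_nonpromoter(regions, tss, upstream = 1000,
                             chrom_lengths = c(chr1 = 10000))
  # window clips to [0, 501): region [0,100) removed, [600,700) kept
  expect_length(kept, 1)
  expect_equal(GenomicRanges::start(kept) - 1, 600)
  expect_length(filter_nonpromoter(regions, tss[0]), 2)
})

test_that("study-region restriction keeps items by midpoint", {
  item <- gr("chr1", 10, 20)  # midpoint 15 (0-based)
  expect_length(restrict_to_regions(item, gr("chr1", 0, 15)), 0)
  expect_length(restrict_to_regions(item, gr("chr1", 0, 16)), 1)
  many <- gr("chr1", c(0, 50, 100), c(10, 60, 110))
  expect_length(restrict_to_regions(many, gr("chr1", 0, 1000)), 3)
  expect_length(restrict_to_regions(many, GenomicRanges::GRanges()), 0)
})

test_that("BED6 roundtrip preserves coordinates and strand", {
  x <- gr("chr2", c(10, 200), c(25, 300), strand = c("+", "-"))
  x$name <- c("a", "b")
  x$score <- c(1, 2)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path)
  expect_equal(GenomicRanges::start(y), GenomicRanges::start(x))
  expect_equal(GenomicRanges::end(y), GenomicRanges::end(x))
  expect_equal(as.character(GenomicRanges::strand(y)),
               as.character(GenomicRanges::strand(x)))
})
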