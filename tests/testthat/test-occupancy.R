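test_that("three-configuration case matches hand enumeration", {
  # L = 2 on 3 bases, all E = 0, mu = 0: configurations {}, {1}, {2}; Z = 3
  r <- occupancy_from_energies(c(0, 0), mu = 0, L = 2)
  expect_equal(exp(r$log_partition), 3, tolerance = 1e-12)
  expect_equal(r$occupancy, c(1, 2, 1) / 3, tolerance = 1e-12)
  expect_equal(r$p_start, c(1, 1) / 3, tolerance = 1e-12)
})

test_that("DP matches exhaustive enumeration on random landscapes", {
  set.seed(101)
  for (rep in 1:120) {
    L <- sample(2:4, 1)
    n <- sample(L:12, 1)
    e <- rnorm(n - L + 1, sd = 2)
    if (runif(1) < 0.3) e[sample(length(e), 1)] <- NA  # masked start
    mu <- rnorm(1, sd = 2)
    dp <- occupancy_from_energies(e, mu = mu, L = L)
    or <- enumerate_occupancy(e, mu = mu, L = L)
    expect_lt(max(abs(dp$occupancy - or$occupancy)), 1e-9)
    expect_lt(max(abs(dp$p_start - or$p_start)), 1e-9)
    expect_equal(dp$log_partition, log(or$Z), tolerance = 1e-9)
  }
})

test_that("DP matches enumeration on model-scored short sequences", {
  m <- toy_model(L = 3)
  set.seed(55)
  for (rep in 1:40) {
    s <- random_dna(sample(3:12, 1))
    land <- score_energies(s, m)
    dp <- occupancy_from_energies(land, mu = 0.5, L = 3)
    or <- enumerate_occupancy(land$energies, mu = 0.5, L = 3)
    expect_lt(max(abs(dp$occupancy - or$occupancy)), 1e-9)
  }
})

test_that("occupancy mass equals L times total start probability", {
  set.seed(7)
  for (rep in 1:30) {
    L <- sample(2:10, 1)
    n <- sample(L:200, 1)
    e <- rnorm(n - L + 1, sd = 3)
    r <- occupancy_from_energies(e, mu = rnorm(1), L = L)
    expect_equal(sum(r$occupancy), L * sum(r$p_start), tolerance = 1e-9)
    expect_true(all(r$occupancy >= 0 & r$occupancy <= 1))
  }
})

test_that("mean occupancy is monotone nondecreasing in the chemical potential", {
  set.seed(13)
  for (rep in 1:20) {
    e <- rnorm(30, sd = 2)
    mus <- sort(rnorm(4, sd = 3))
    means <- vapply(mus, function(m) {
      mean(occupancy_from_energies(e, m, L = 5)$occupancy)
    }, numeric(1))
    expect_true(all(diff(means) >= -1e-12))
  }
  # mu -> -Inf limit: vanishing occupancy
  e <- rnorm(20)
  r <- occupancy_from_energies(e, mu = -60, L = 4)
  expect_true(all(r$occupancy < 1e-20))
})

test_that("per-base monotonicity can fail, and the DP tracks the oracle when it does", {
  # raising mu densifies packing, which can reroute footprints away from a
  # base covered only by a weakly favoured window; pointwise occupancy is
  # therefore NOT monotone, and the exhaustive enumeration agrees with the
  # DP about exactly where it drops
  e <- c(3.564, -1.419, -2.238, -1.888, 2.336, -0.583)
  lo <- occupancy_from_energies(e, mu = 1.1217, L = 3)$occupancy
  hi <- occupancy_from_energies(e, mu = 2.0916, L = 3)$occupancy
  expect_lt(min(hi - lo), -1e-6)
  expect_gt(mean(hi) - mean(lo), 0)
  or_lo <- enumerate_occupancy(e, mu = 1.1217, L = 3)$occupancy
  or_hi <- enumerate_occupancy(e, mu = 2.0916, L = 3)$occupancy
  expect_lt(max(abs((hi - lo) - (or_hi - or_lo))), 1e-9)
})

test_that("degenerate inputs behave as contracted", {
  # no legal footprint: Z = 1, occupancy identically zero
  r <- occupancy_from_energies(numeric(0), mu = 0, L = 5)
  expect_equal(r$log_partition, 0)
  expect_true(all(r$occupancy == 0))
  m <- toy_model(L = 4)
  land <- score_energies("AC", m)
  r2 <- occupancy_from_energies(land, mu = 0, L = 4)
  expect_equal(r2$occupancy, c(0, 0))
  expect_equal(r2$log_partition, 0)
  expect_error(occupancy_from_energies(c(0, Inf), mu = 0, L = 2), "non-finite")
})

test_that("log-space recursions survive extreme energies without overflow", {
  e <- rep(c(-50, 50), length.out = 2000)
  r <- occupancy_from_energies(e, mu = 0, L = 10)
  expect_true(all(is.finite(r$occupancy)))
  expect_true(is.finite(r$log_partition))
  expect_true(all(r$occupancy >= 0 & r$occupancy <= 1))
})

test_that("uniform landscapes give symmetric profiles with depressed edges", {
  # open boundaries impose density oscillations on a uniform hard-core gas
  # (no flat plateau at finite length), but the profile is mirror-symmetric,
  # the L-1 edge bases ramp up from below, and the whole curve matches
  # exhaustive enumeration
  m <- toy_model(L = 3)
  m$dinuc_logprob <- matrix(m$bg_logprob, nrow = 2, ncol = 16, byrow = TRUE,
                            dimnames = dimnames(m$dinuc_logprob))
  n <- 30
  set.seed(2)
  tr <- intrinsic_occupancy(c(chr1 = random_dna(n)), m, mu = 0)
  v <- tr$values$chr1
  expect_equal(v, rev(v), tolerance = 1e-9)
  expect_true(v[1] < v[2] && v[2] < v[3])
  expect_true(all(v[1:2] < mean(v)))
  or <- enumerate_occupancy(rep(0, n - 2), mu = 0, L = 3)
  expect_equal(v, or$occupancy, tolerance = 1e-9)
})

test_that("chromosomes are independent and reruns are byte-identical", {
  m <- toy_model(L = 3)
  set.seed(9)
  g <- c(chrA = random_dna(40), chrB = random_dna(25))
  both <- intrinsic_occupancy(g, m, mu = 0.2)
  alone <- lapply(names(g), function(ch) {
    intrinsic_occupancy(g[ch], m, mu = 0.2)$values[[ch]]
  })
  expect_identical(both$values$chrA, alone[[1]])
  expect_identical(both$values$chrB, alone[[2]])
  again <- intrinsic_occupancy(g, m, mu = 0.2)
  expect_identical(both$values, again$values)
})

test_that("strand symmetry holds at the whole-chromosome level", {
  m <- toy_model(L = 4)
  set.seed(23)
  s <- random_dna(300)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  t1 <- intrinsic_occupancy(c(chr = s), m, mu = 1)
  t2 <- intrinsic_occupancy(c(chr = rc), m, mu = 1)
  expect_lt(max(abs(t1$values$chr - rev(t2$values$chr))), 1e-9)
})

test_that("mu calibration hits the target mean occupancy", {
  m <- toy_model(L = 5)
  set.seed(31)
  g <- c(chr1 = random_dna(2000))
  tr <- intrinsic_occupancy(g, m, mu = NULL, target_occupancy = 0.6)
  expect_equal(mean(tr$values$chr1), 0.6, tolerance = 1e-3)
  expect_true(is.numeric(attr(tr, "mu")))
})

test_that("bases coverable by no footprint stay defined with zero occupancy", {
  m <- toy_model(L = 4)
  # an N-run wider than L isolates bases no footprint can cover
  s <- paste0(random_dna(10), "NNNNNN", random_dna(10))
  tr <- intrinsic_occupancy(c(chr = s), m, mu = 5)
  v <- tr$values$chr
  expect_false(anyNA(v))
  expect_true(all(v[13:14] == 0))  # deep inside the N-run
  expect_true(all(v[1:5] > 0))
})
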