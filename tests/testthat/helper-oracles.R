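# Independent oracles used to freeze expected values. These deliberately
# share no code with the package implementations they check.

# Exhaustive enumeration of all legal nucleosome configurations (sets of
# non-overlapping L-base footprint starts); returns per-base occupancy and
# the partition function.
enumerate_occupancy <- function(energies, mu, L) {
  S <- length(energies)
  n <- S + L - 1
  w <- exp(mu - energies)
  w[is.na(w)] <- 0
  Z <- 0
  occ <- numeric(max(n, 0))
  configs <- list()
  gen <- function(i, chosen) {
    if (i > S) {
      configs[[length(configs) + 1L]] <<- chosen
      return()
    }
    gen(i + 1, chosen)
    if (length(chosen) == 0 || i - chosen[length(chosen)] >= L) {
      gen(i + 1, c(chosen, i))
    }
  }
  gen(1, integer(0))
  for (cf in configs) {
    weight <- if (length(cf)) prod(w[cf]) else 1
    Z <- Z + weight
    for (s in cf) occ[s:(s + L - 1)] <- occ[s:(s + L - 1)] + weight
  }
  list(occupancy = occ / Z, Z = Z,
       p_start = vapply(seq_len(S), function(i) {
         sum(vapply(configs, function(cf) {
           if (i %in% cf) (if (length(cf)) prod(w[cf]) else 1) else 0
         }, numeric(1)))
       }, numeric(1)) / Z)
}

# Global exhaustive leftmost-start/longest-extent search for maximal
# CpG-island intervals; O(n^2) via prefix sums, no seeding.
brute_cpg_islands <- function(sequence, min_length = 200, min_gc = 0.5,
                              min_oe = 0.6) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  isC <- ch == "C"
  isG <- ch == "G"
  cpg <- isC & c(isG[-1], FALSE)
  cC <- c(0, cumsum(isC)); cG <- c(0, cumsum(isG))
  cGC <- c(0, cumsum(isC | isG)); cP <- c(0, cumsum(cpg))
  out <- NULL
  s <- 1
  while (s + min_length - 1 <= n) {
    e <- (s + min_length - 1):n
    len <- e - s + 1
    nC <- cC[e + 1] - cC[s]; nG <- cG[e + 1] - cG[s]
    gc <- cGC[e + 1] - cGC[s]; np <- cP[e] - cP[s]
    ok <- gc >= min_gc * len & np >= 1 & np * len >= min_oe * nC * nG
    if (any(ok)) {
      best <- e[max(which(ok))]
      out <- rbind(out, c(s, best))
      s <- best + 1
    } else {
      s <- s + 1
    }
  }
  out
}

# direct positional dinucleotide count over windows plus reverse complements
brute_dinuc_prob <- function(windows, position, dinuc, pseudocount) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  all_w <- c(windows, vapply(windows, rc, character(1)))
  hits <- sum(vapply(all_w, function(w) {
    substr(w, position, position + 1) == dinuc
  }, logical(1)))
  (hits + pseudocount) / (length(all_w) + 16 * pseudocount)
}

# textbook scalar correlations (closed forms, no library calls)
pearson_scalar <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
spearman_scalar <- function(x, y) {
  pearson_scalar(rank(x), rank(y))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a fixed small model with non-trivial energies, for DP tests
toy_model <- function(L = 3, seed = 42) {
  set.seed(seed)
  fit_nucleosome_model(
    bound_windows = replicate(8, random_dna(L, gc = 0.7)),
    background_seqs = replicate(4, random_dna(50, gc = 0.4)),
    pseudocount = 0.5, L = L
  )
}

small_track <- function(...) {
  genome_track(list(...))
}
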