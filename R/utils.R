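#' @useDynLib nucoccupancy, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor pt rpois runif rlnorm rgeom rbinom uniroot setNames
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

.BASES <- c("A", "C", "G", "T")
.DINUCS <- paste0(rep(.BASES, each = 4), rep(.BASES, 4))

# lookup table from char code to base code 1..4 (case-insensitive); N and
# every other character map to NA
.base_code_table <- local({
  tab <- rep(NA_integer_, 256)
  for (i in seq_along(.BASES)) {
    tab[utf8ToInt(.BASES[i])] <- i
    tab[utf8ToInt(tolower(.BASES[i]))] <- i
  }
  tab
})

#' Encode a DNA string as integer base codes
#'
#' A/C/G/T (case-insensitive) map to 1..4; N and any other character to `NA`.
#'
#' @param sequence a single character string.
#' @return integer vector of length `nchar(sequence)`.
#' @keywords internal
seq_to_codes <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  .base_code_table[utf8ToInt(sequence)]
}

codes_to_seq <- function(codes) {
  chars <- c(.BASES, "N")[ifelse(is.na(codes), 5L, codes)]
  paste(chars, collapse = "")
}

# dinucleotide code 1..16 at each start position (length n-1); NA where
# either base is ambiguous
dinuc_codes <- function(codes) {
  n <- length(codes)
  if (n < 2L) return(integer(0))
  4L * (codes[-n] - 1L) + codes[-1L]
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Derive a stage- or chromosome-specific seed from a master seed
#'
#' Makes every stochastic stage individually reproducible from one master
#' seed while keeping streams distinct across stages.
#'
#' @param seed master seed (integer).
#' @param label stage/chromosome label.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 131 + k) %% 2147480009
  as.integer(((abs(seed) %% 1000003) * 2011 + h) %% 2147483647)
}

# coerce a genome argument (DNAStringSet or named character vector) to a
# named character vector of chromosome sequences
as_genome_seqs <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- genome
  } else {
    stop("`genome` must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("genome sequences must be named by chromosome")
  }
  seqs
}

#' @importFrom methods is
NULL
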