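# Low-level sequence helpers shared across modules. Sequences are plain
# character strings over {A,C,G,T,N}; byte-level coding keeps the hot paths
# (scanning, GC computation, one-hot encoding) allocation-light.

.BASES <- c("A", "C", "G", "T")

# byte -> code lookup: A=1 C=2 G=3 T=4 N=5, 0 for anything else
.CODE_MAP <- local({
  m <- integer(256)
  m[utf8ToInt("A") + 1L] <- 1L
  m[utf8ToInt("C") + 1L] <- 2L
  m[utf8ToInt("G") + 1L] <- 3L
  m[utf8ToInt("T") + 1L] <- 4L
  m[utf8ToInt("N") + 1L] <- 5L
  m
})

# complement of the integer codes (N maps to itself)
.COMP_CODE <- c(4L, 3L, 2L, 1L, 5L)

seq_to_codes <- function(sequence) {
  codes <- .CODE_MAP[as.integer(charToRaw(sequence)) + 1L]
  if (any(codes == 0L)) {
    bad <- unique(strsplit(sequence, "")[[1]])
    bad <- setdiff(bad, c(.BASES, "N"))
    stop("illegal character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  codes
}

codes_to_seq <- function(codes) {
  paste(c(.BASES, "N")[codes], collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector; `N` is preserved.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    codes_to_seq(rev(.COMP_CODE[seq_to_codes(s)]))
  }, character(1), USE.NAMES = FALSE)
}

#' GC fraction of DNA strings
#'
#' Fraction of `G`/`C` among non-`N` bases; `NaN` for all-`N` input.
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  vapply(x, function(s) {
    r <- charToRaw(s)
    gc <- sum(r == as.raw(71L) | r == as.raw(67L))
    n <- sum(r == as.raw(78L))
    gc / (length(r) - n)
  }, numeric(1), USE.NAMES = FALSE)
}

n_fraction <- function(x) {
  vapply(x, function(s) {
    r <- charToRaw(s)
    mean(r == as.raw(78L))
  }, numeric(1), USE.NAMES = FALSE)
}

# Deterministic per-stage seed derived from the global seed, so changing one
# stage's configuration never reshuffles another stage's randomness.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Extract [start, end] (1-based inclusive) from a genome (named character
# vector of chromosome sequences).
genome_substr <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  substr(genome[[chrom]], start, end)
}
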