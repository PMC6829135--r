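# Internal helpers shared across modules.

# Deterministic per-stage seed derived from one global seed so that pipeline
# stages can be rerun independently and still be reproducible.
substream_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * ((seq_along(codes) - 1L) %% 89L + 3L)) %% 1000003
  as.integer((as.numeric(seed) %% 2097143) * 1009 + h * 31 + 17) %% 2147483629L
}

# Arithmetic rounding (half away from zero), the convention used by the
# reported percentage tables.  base::round() rounds half to even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage of num/den formatted with one decimal, half-up ("6.8").
format_pct <- function(num, den, digits = 1) {
  sprintf(paste0("%.", digits, "f"), round_half_up(100 * num / den, digits))
}

dna_alphabet <- c("A", "C", "G", "T")

rand_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(dna_alphabet, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# Longest strictly-increasing subsequence of integer-valued x; returns the
# indices of one such subsequence. O(n log n) patience sorting.
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tails <- numeric(n)   # smallest tail value of an increasing subsequence of length j
  tidx <- integer(n)    # index in x of that tail
  prev <- integer(n)
  len <- 0L
  for (i in seq_len(n)) {
    # first j with tails[j] >= x[i]  (strict increase: equal values replace)
    j <- findInterval(x[i] - 0.5, tails[seq_len(len)]) + 1L
    prev[i] <- if (j > 1L) tidx[j - 1L] else 0L
    tails[j] <- x[i]
    tidx[j] <- i
    if (j > len) len <- j
  }
  k <- tidx[len]
  out <- integer(0)
  while (k > 0L) {
    out <- c(k, out)
    k <- prev[k]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
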