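# Internal helpers shared across stages.

# Derive n reproducible stage seeds from one master seed.  Keeps every
# derived seed strictly below 2^31 so set.seed() accepts it everywhere.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  stopifnot(length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
  as.list(sample.int(2147483646L, n))
}

msg <- function(..., quiet = FALSE) {
  if (!quiet) message(...)
}

# Upper-triangle values of a symmetric matrix (i < j).
upper_values <- function(m) m[upper.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a
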