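# Internal helpers shared across the engines.

# Evaluate `code` under a temporary RNG seed, restoring global RNG state after.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-iteration seed streams derived from one master seed.
# Split seeds are drawn first so that engines sharing a master seed (e.g.
# split-half reliability and the cross-validated factor analysis) operate on
# identical trial splits; permutation/bootstrap streams use a shifted master
# so they never collide with the split stream.
iteration_seeds <- function(seed, n, stream = c("split", "perm", "boot", "draw")) {
  stream <- match.arg(stream)
  offset <- c(split = 0L, perm = 1L, boot = 2L, draw = 3L)[[stream]]
  with_seed_(as.integer(seed) + offset, sample.int(.Machine$integer.max, n))
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g].", name, lo, hi))
  }
  as.numeric(x)
}
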