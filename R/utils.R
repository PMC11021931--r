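## Derive a deterministic substream seed from a master seed.  Keeps results
## reproducible while decoupling generation, bootstrap and permutation draws.
## The Lehmer step keeps derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + stream) %% 2147483647)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

## sample() without its length-1 surprise
sample_int <- function(n, size, replace = FALSE) {
  sample.int(n, size = size, replace = replace)
}
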