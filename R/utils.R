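# Seed plumbing. Seeded operations must be reproducible without clobbering
# the caller's RNG stream, so seeds are applied locally and the global state
# restored afterwards.

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic child seeds from a master seed, kept within 32-bit range.
derive_seeds <- function(seed, n) {
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  sample.int(.Machine$integer.max - 1L, n)
}

# Shannon entropy (bits) of a probability vector with 0 log 0 = 0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
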