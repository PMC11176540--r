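# internal helpers: seeded evaluation and argument checks

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All randomness in the package flows
# through this so identical seeds give bit-identical results.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; keeps results < 2^31 - 1.
derive_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 7919 + 12345) %% 2147483647
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x))
    stop(sprintf("%s contains a non-finite value (first at index %d)", what, bad[1L]))
  }
  invisible(TRUE)
}

check_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("%s must be a positive finite scalar", what))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
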