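# Run code under a local RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package take an explicit seed and go
# through this helper; no function disturbs the global RNG stream.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# derive a bounded child seed from a base seed and an index (< 2^31)
child_seed <- function(seed, i) {
  (as.numeric(seed) * 1000L + i) %% 2147483647
}
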