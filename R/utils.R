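# shared helpers

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific 32-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %%
               2147483640) + 1L
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
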