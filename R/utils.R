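## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards. Keeps every stochastic entry point
## reproducible without clobbering the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}
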