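## Run code under a temporary RNG seed, restoring the caller's RNG state.
## seed = NULL leaves the RNG untouched (draws advance the global stream).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
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

## Proportion formatted the way clinical reports print it: one decimal.
format_pct <- function(x, digits = 1) sprintf(paste0("%.", digits, "f%%"), 100 * x)
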