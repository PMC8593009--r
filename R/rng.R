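# Independent RNG streams: the engine (e.g. cued-hole selection) and the agent
# draw from separate streams so task randomness and behaviour are separately
# reproducible. Streams are plain saved .Random.seed states swapped in around
# each draw; the caller's RNG state is always restored.

new_rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  state <- get(".Random.seed", envir = globalenv())
  if (had_seed) {
    assign(".Random.seed", old, envir = globalenv())
  } else {
    rm(".Random.seed", envir = globalenv())
  }
  stream <- new.env(parent = emptyenv())
  stream$state <- state
  class(stream) <- "rng_stream"
  stream
}

with_stream <- function(stream, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(expr)
}
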