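# Reproducible randomness helpers.
#
# Generators that must be chunk-invariant (the closed-loop LFP plant) draw
# from private RNG substreams: each stream stores its own .Random.seed and
# swaps it in only while drawing, so consumption order is independent of the
# caller's RNG use and of how the signal is chunked.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- with_seed(seed, get(".Random.seed", globalenv()))
  e
}

rng_draw <- function(stream, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  out <- fn()
  stream$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv())
  out
}

# derive a bounded child seed from a base seed and a tag (keeps seeds < 2^31)
child_seed <- function(seed, tag) {
  (as.numeric(seed) * 1103515245 + tag * 12345) %% 2147483647
}
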