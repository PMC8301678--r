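# Splittable random-number streams built on the L'Ecuyer-CMRG generator.
#
# A single global seed governs all draws; each sample in a simulated study
# draws from its own substream keyed by the sample index, so any sample can be
# regenerated on its own without replaying the whole study. The user's global
# RNG state is saved and restored around every draw.

new_stream <- function(seed, substream = 0L) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("`seed` must be a single finite number")
  state <- local({
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    suppressWarnings(set.seed(as.integer(seed) %% .Machine$integer.max,
                              kind = "L'Ecuyer-CMRG"))
    get(".Random.seed", envir = globalenv())
  })
  for (i in seq_len(substream)) state <- parallel::nextRNGStream(state)
  env <- new.env(parent = emptyenv())
  env$state <- state
  class(env) <- "morphotest_stream"
  env
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Evaluate `expr` with the stream's state installed as the global RNG state,
# then capture the advanced state back into the stream.
stream_eval <- function(stream, expr) {
  stopifnot(inherits(stream, "morphotest_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  assign(".Random.seed", stream$state, envir = globalenv())
  res <- force(expr)
  stream$state <- get(".Random.seed", envir = globalenv())
  res
}
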