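# Seed handling: run seeded code without disturbing the caller's RNG
# stream. Returns the previous .Random.seed (or NULL) for .restore_rng().
.preserve_rng <- function(seed) {
  prev <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  if (!is.null(seed)) set.seed(as.integer(seed))
  prev
}

.restore_rng <- function(prev) {
  if (is.null(prev)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", prev, envir = globalenv())
  }
  invisible(NULL)
}
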