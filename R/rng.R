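# Seed scoping and derivation.  All randomized operations take an explicit
# integer seed and leave the caller's RNG state untouched; stage-level seeds
# are derived deterministically from a run seed so stages can be re-run
# independently.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed for a named stage
#'
#' Deterministic hash of (seed, stage name) onto \code{[0, 2^31 - 2]}, so each
#' pipeline stage gets an independent, reproducible RNG stream.
#'
#' @param seed integer parent seed.
#' @param stage character stage name.
#' @return integer child seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- as.double(seed %% 2147483647L)
  for (byte in utf8ToInt(stage)) {
    h <- (h * 131 + byte) %% 2147483647
  }
  as.integer(h)
}
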