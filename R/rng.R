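# Splittable-seed contract: every stochastic operation takes one integer
# seed; sub-streams are derived deterministically so fixtures never depend
# on global RNG state or call order.

#' Derive a deterministic sub-seed
#'
#' @param seed Master integer seed.
#' @param stream Integer stream identifier.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream = 1L) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 + as.numeric(stream) * 7919 + 12345
  as.integer(x %% (m - 1) + 1)
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
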