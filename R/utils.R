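# Internal helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which would
# make turnover counts like round(0.5 * 10) depend on IEEE parity; patch
# bookkeeping uses the conventional half-up rule instead.
round_half_up <- function(x) {
  floor(x + 0.5)
}

clamp01 <- function(x) {
  pmin(1, pmax(0, x))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Derive a reproducible stream seed from a base seed and indices
#'
#' Maps `(base_seed, stream, index)` to an integer in `[1, 2^31 - 2]` with a
#' fixed linear-congruential mix. Used by [run_experiment()] so that every
#' (cell, iteration) pair owns its own seed: results are then independent of
#' worker count and of the order cells are executed in.
#'
#' @param base_seed integer base seed of the whole experiment.
#' @param stream integer stream id (e.g. a scenario-cell index).
#' @param index integer index within the stream (e.g. an iteration number).
#' @return a single integer seed.
#' @examples
#' derive_seed(1, 3, 7)
#' @export
derive_seed <- function(base_seed, stream, index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(as.numeric(base_seed)) %% m)
  h <- (h * 48271 + as.numeric(stream) * 15485863) %% m
  h <- (h * 69621 + as.numeric(index) * 2654435) %% m
  as.integer(h %% (m - 1L) + 1)
}
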