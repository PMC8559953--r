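#' Independent, restorable random streams for MCA simulation
#'
#' `mca_rng()` creates a self-contained uniform random stream that does not
#' disturb (and is not disturbed by) the session's global RNG. Each stream
#' stores its own Mersenne-Twister state; draws swap the state in and out of
#' `.Random.seed`, so perturbation streams are reproducible and statistically
#' independent across simulations.
#'
#' @param seed integer seed (kept below 2^31).
#' @return an object of class `mca_rng`.
#' @seealso [derive_seed()] for counter-based sub-seed derivation.
#' @export
mca_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "mca_rng"
  e
}

#' Draw uniforms from an MCA stream
#'
#' @param rng an [mca_rng()] stream.
#' @param n number of draws.
#' @param min,max range of the uniform; defaults to the centred ulp-scale
#'   range (-1/2, 1/2) used by the rounding-noise model.
#' @return numeric vector of length `n`.
#' @export
rng_unif <- function(rng, n, min = -0.5, max = 0.5) {
  stopifnot(inherits(rng, "mca_rng"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  u <- stats::runif(n, min = min, max = max)
  rng$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  u
}

#' Counter-based sub-seed derivation
#'
#' Deterministically mixes a base seed with one or more counters (simulation
#' index, stage index, ...) into a new seed below 2^31, so that repeated runs
#' are bit-reproducible while distinct counters give independent streams.
#'
#' @param seed base integer seed.
#' @param ... integer counters.
#' @return a single integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime; products stay < 2^53
  s <- (abs(as.numeric(seed)) %% m)
  for (k in as.numeric(c(...))) {
    s <- (s * 48271 + (k + 1) * 30269 + 11) %% m
  }
  as.integer(s %% (m - 2) + 1)
}
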