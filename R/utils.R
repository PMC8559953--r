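# Evaluate `code` under a temporary global RNG seed, restoring the previous
# RNG state afterwards (base-R stand-in for withr::with_seed).
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Vectorize the upper triangle of a square matrix
#'
#' Edge-level metrics and distances operate on the vectorized strict upper
#' triangle of the (symmetric) adjacency matrix.
#'
#' @param m square matrix.
#' @return numeric vector of the entries above the diagonal (column-major).
#' @export
upper_triangle <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[upper.tri(m)]
}

# FNV-1a string hash (hex), used to stamp outputs with their config identity.
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b)) + 2^30
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Sample standard deviation with the n-1 denominator, no NA handling.
sd_unbiased <- function(x) stats::sd(x)

# Matrix-wise max absolute difference.
max_abs_diff <- function(a, b) max(abs(a - b))
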