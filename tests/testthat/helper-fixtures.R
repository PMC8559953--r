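# Small seeded fixtures shared across test files. Everything is generated in
# code at test time; sizes are deliberately tiny so a full suite run stays
# fast while exercising the same code paths as the full presets.

tiny_design <- function(n_subjects = 3, n_sessions = 2, n_subsamples = 2,
                        n_volumes = 24, n_b0 = 3, n_sims = 2,
                        pipelines = "det", modes = "dense") {
  study_design(n_subjects, n_sessions, n_subsamples, n_volumes, n_b0,
               n_sims, pipelines = pipelines, modes = modes)
}

tiny_cohort <- function(seed = 7, n_nodes = 8, design = tiny_design(), ...) {
  generate_cohort(design, n_nodes = n_nodes, seed = seed, ...)
}

# One reconstructed execution grid reused by stability/discriminability
# tests within a file (built lazily, cached per test-file process).
local({
  cache <- new.env(parent = emptyenv())
  tiny_set <<- function(seed = 7, n_sims = 2, pipelines = "det",
                        modes = "dense", t = 52) {
    key <- paste(seed, n_sims, paste(pipelines, collapse = ""),
                 paste(modes, collapse = ""), t, sep = "_")
    if (is.null(cache[[key]])) {
      co <- tiny_cohort(seed, design = tiny_design(pipelines = pipelines,
                                                   modes = modes,
                                                   n_sims = n_sims))
      cache[[key]] <- reconstruct_cohort(co, t = t, base_seed = seed)
    }
    cache[[key]]
  }
})

# Random symmetric nonnegative weight matrix with zero diagonal.
random_connectome <- function(n, density = 0.7, seed = 1) {
  with_seed <- function(s, code) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); force(code)
  }
  with_seed(seed, {
    W <- matrix(0, n, n)
    up <- which(upper.tri(W))
    on <- sample(up, ceiling(density * length(up)))
    W[on] <- runif(length(on), 0.1, 2)
    W <- W + t(W)
    diag(W) <- 0
    W
  })
}

# Evaluate an expression under a temporary seed, restoring the RNG state.
with_seed_local <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
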