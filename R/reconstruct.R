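#' Reconstruct a connectome from one sample's measurements
#'
#' A deterministic-given-seed numeric chain standing in for tractography:
#' baseline normalization, a per-node signal-model fit via normal-equation
#' solves, outer-product accumulation of node factors into edge weights, a
#' residual-based quality scaling pass, nonnegativity clipping,
#' symmetrization, and total-weight normalization. Every floating-point
#' stage is routed through the MCA instrumentation layer, so perturbations
#' propagate realistically; with `profile$density == "off"` repeated calls
#' are bit-identical.
#'
#' The `"det"` variant runs the chain once on the full measurement set; the
#' `"prob"` variant averages the edge-accumulation over `n_resample`
#' bootstrap draws of the directional measurements, using an internal random
#' state that is fixed for all analyses (independent of the perturbation
#' seed), so that observed variability is attributable to the injected noise
#' alone.
#'
#' Layer tags: measurement reads, edge accumulation (graph building),
#' quality scaling and final normalization model interpreter-level data
#' handling and are `"data-layer"` ops (perturbed under both densities);
#' the baseline mean/normalization, Gram matrix, normal-equation products,
#' linear solve, prediction, resample averaging and symmetrization model
#' BLAS/LAPACK-style kernels and are `"core-numeric"` (perturbed under the
#' dense density only). The sparse-perturbed op set is therefore a strict
#' subset of the dense one. Under the sparse density, measurement reads
#' return the stored data with one frozen ulp-scale perturbation per
#' element per simulation (data-at-rest model); under dense, every read is
#' perturbed independently per call.
#'
#' @param msmt measurement set (`Y`, `X`, `b0`) as produced by
#'   [generate_cohort()] / [split_subsamples()].
#' @param pipeline `"det"` or `"prob"`.
#' @param profile an [mca_profile()].
#' @param rng an [mca_rng()] perturbation stream.
#' @param key optional sample-provenance list stored on the result.
#' @param n_resample internal bootstrap draws for the `"prob"` variant.
#' @param ridge ridge stabilizer added to the normal equations.
#' @param internal_seed fixed internal random state of the `"prob"` variant.
#' @return an object of class `cs_connectome`: list with the symmetric
#'   nonnegative `weights` matrix (zero diagonal, unit total weight) and the
#'   provenance `key`. Degenerate all-zero measurements yield an empty-graph
#'   warning and a zero matrix.
#' @export
reconstruct_connectome <- function(msmt, pipeline = c("det", "prob"),
                                   profile = mca_profile(density = "off"),
                                   rng = mca_rng(profile$seed),
                                   key = list(), n_resample = 5L,
                                   ridge = 1e-8, internal_seed = 20210401L) {
  pipeline <- match.arg(pipeline)
  Y <- msmt$Y
  X <- msmt$X
  if (any(!is.finite(Y))) stop("non-finite measurements")
  n_nodes <- ncol(Y)
  if (all(Y == 0)) {
    warning("degenerate all-zero measurements; returning empty graph")
    return(new_connectome(matrix(0, n_nodes, n_nodes), key))
  }

  # Data-at-rest noise for the sparse density: one frozen ulp perturbation
  # per stored measurement per simulation, reused coherently at every read.
  frozen_xi <- NULL
  if (profile$density == "sparse" && profile$mode != "off") {
    frozen_xi <- rng_unif(rng, length(Y))
  }
  read_data <- function() {
    if (!mca_active(profile, "data-layer")) return(Y)
    if (!is.null(profile$trace)) {
      profile$trace$ops <- c(profile$trace$ops, "read|data-layer")
    }
    if (!is.null(frozen_xi)) {
      inexact(Y, t = profile$t, xi = frozen_xi)
    } else {
      inexact(Y, t = profile$t, rng = rng)
    }
  }

  p <- ncol(X)
  fit_once <- function(rows) {
    Xr <- X[rows, , drop = FALSE]
    b0r <- msmt$b0[rows]
    # Pass 1: baseline signal per node from the non-directional volumes.
    Y1 <- read_data()[rows, , drop = FALSE]
    s0 <- p_instr(function(m) colSums(m) / sum(b0r),
                  list(Y1[b0r, , drop = FALSE]), profile, rng,
                  "core-numeric", "b0-mean")
    if (any(s0 == 0)) stop("invalid operand: zero baseline signal")
    # Pass 2: normalized signal enters the data side of the normal equations.
    Y2 <- read_data()[rows, , drop = FALSE]
    Yn <- p_instr(function(a, b) sweep(a, 2, b, "/"), list(Y2, s0),
                  profile, rng, "core-numeric", "b0-normalize")
    XtX <- p_instr(crossprod, list(Xr), profile, rng, "core-numeric", "gram")
    XtY <- p_instr(crossprod, list(Xr, Yn), profile, rng, "core-numeric", "xty")
    B <- p_instr(function(A, b) solve(A + ridge * diag(p), b),
                 list(XtX, XtY), profile, rng, "core-numeric", "solve")
    # Edge accumulation: outer products of the directional node factors.
    G <- t(B[-1L, , drop = FALSE])
    W <- p_instr(tcrossprod, list(G), profile, rng, "data-layer",
                 "edge-accumulate")
    # Pass 3: residual-based quality weighting of the whole graph.
    Y3 <- read_data()[rows, , drop = FALSE]
    Yn3 <- p_instr(function(a, b) sweep(a, 2, b, "/"), list(Y3, s0),
                   profile, rng, "core-numeric", "b0-normalize")
    P <- p_instr(`%*%`, list(Xr, B), profile, rng, "core-numeric", "predict")
    R <- p_instr(`-`, list(Yn3, P), profile, rng, "core-numeric", "residual")
    q <- p_instr(function(r) 1 / (1 + sum(r * r) / length(r)),
                 list(R), profile, rng, "data-layer", "quality")
    p_instr(`*`, list(W, q), profile, rng, "data-layer", "quality-scale")
  }

  if (pipeline == "det") {
    W <- fit_once(seq_len(nrow(Y)))
  } else {
    dir_idx <- which(!msmt$b0)
    acc <- NULL
    for (r in seq_len(n_resample)) {
      boot <- with_seed(derive_seed(internal_seed, r, nrow(Y)), {
        sample(dir_idx, length(dir_idx), replace = TRUE)
      })
      rows <- c(which(msmt$b0), sort(boot))
      Wr <- fit_once(rows)
      acc <- if (is.null(acc)) Wr else {
        p_instr(`+`, list(acc, Wr), profile, rng, "core-numeric", "accumulate")
      }
    }
    W <- p_instr(`/`, list(acc, n_resample), profile, rng,
                 "core-numeric", "average")
  }

  W <- p_instr(function(w) (w + t(w)) / 2, list(W), profile, rng,
               "core-numeric", "symmetrize")
  W <- pmax(W, 0)           # structural nonnegativity clip
  diag(W) <- 0
  tot <- p_instr(sum, list(W), profile, rng, "data-layer", "norm-sum")
  if (tot > 0) {
    W <- p_instr(`/`, list(W, tot), profile, rng, "data-layer", "normalize")
  }
  # elementwise RR noise in the final ops is not symmetric; graph-build
  # symmetry is structural, so mirror once more (uninstrumented)
  W <- (W + t(W)) / 2
  W <- pmax(W, 0)
  diag(W) <- 0
  dimnames(W) <- NULL
  new_connectome(W, key)
}

new_connectome <- function(weights, key = list()) {
  structure(list(weights = weights, key = key), class = "cs_connectome")
}

#' @export
print.cs_connectome <- function(x, ...) {
  cat(sprintf("<cs_connectome> %d nodes, %d edges%s\n",
              nrow(x$weights), sum(upper_triangle(x$weights) > 0),
              if (length(x$key)) paste0(" [", key_string(x$key), "]") else ""))
  invisible(x)
}

key_string <- function(key) {
  paste(vapply(names(key), function(n) paste0(n, "=", key[[n]]), character(1)),
        collapse = " ")
}

#' Reconstruct every execution of a cohort's experiment grid
#'
#' Runs, for each sample x pipeline x instrumentation mode, one unperturbed
#' reference execution (`sim = 0`, density off) plus `n_sims` perturbed
#' simulations with independent streams, mirroring the execution grid of the
#' study design.
#'
#' @param cohort a [generate_cohort()] result.
#' @param pipelines,modes,n_sims grid; default from the cohort's design.
#' @param t virtual precision of the perturbed executions. The default is
#'   52 bits rather than 53: in a pure double-precision carry, Eq-style
#'   noise at t = 53 is strictly below half an ulp and is always rounded
#'   away, so 52 is the finest virtual precision whose perturbations
#'   survive IEEE-754 rounding (compiler-level tools escape this by
#'   injecting noise on the exact pre-rounding result in extended
#'   precision); see the methods vignette.
#' @param base_seed seed from which all per-simulation streams derive.
#' @param samples optional subset of manifest row indices to reconstruct.
#' @return an object of class `cs_connectome_set`: list with `connectomes`
#'   (list of `cs_connectome`) and `index` (data frame of subject, session,
#'   subsample, pipeline, mode, sim; `sim = 0` is the reference).
#' @export
reconstruct_cohort <- function(cohort, pipelines = cohort$design$pipelines,
                               modes = cohort$design$modes,
                               n_sims = cohort$design$n_sims, t = 52L,
                               base_seed = 1L, samples = NULL) {
  stopifnot(inherits(cohort, "cs_cohort"))
  man <- cohort$samples
  if (is.null(samples)) samples <- seq_len(nrow(man))
  conns <- list()
  idx <- list()
  off <- mca_profile(t = t, mode = "off", density = "off")
  for (si in samples) {
    subj <- man$subject[si]; sess <- man$session[si]; sub <- man$subsample[si]
    msmt <- cohort$measurements[[subj]][[sess]][[sub]]
    for (pi in seq_along(pipelines)) {
      pl <- pipelines[pi]
      for (mi in seq_along(modes)) {
        mode <- modes[mi]
        key0 <- list(subject = subj, session = sess, subsample = sub,
                     pipeline = pl, mode = mode, sim = 0L)
        conns[[length(conns) + 1L]] <- reconstruct_connectome(
          msmt, pl, off, mca_rng(1L), key = key0)
        idx[[length(idx) + 1L]] <- key0
        if (n_sims >= 1) {
          prof <- mca_profile(t = t, mode = "rr", density = mode,
                              seed = derive_seed(base_seed, si, pi, mi))
          for (k in seq_len(n_sims)) {
            keyk <- modifyList(key0, list(sim = as.integer(k)))
            conns[[length(conns) + 1L]] <- reconstruct_connectome(
              msmt, pl, prof, mca_rng(derive_seed(prof$seed, k)), key = keyk)
            idx[[length(idx) + 1L]] <- keyk
          }
        }
      }
    }
  }
  index <- do.call(rbind, lapply(idx, as.data.frame))
  structure(list(connectomes = conns, index = index),
            class = "cs_connectome_set")
}

#' @export
print.cs_connectome_set <- function(x, ...) {
  cat(sprintf("<cs_connectome_set> %d executions (%d reference)\n",
              nrow(x$index), sum(x$index$sim == 0)))
  invisible(x)
}

#' Subset a connectome set by index predicate
#' @param set a [reconstruct_cohort()] result.
#' @param which logical or integer row selector on `set$index`.
#' @return a `cs_connectome_set` restricted to the selected executions.
#' @export
subset_connectomes <- function(set, which) {
  ii <- if (is.logical(which)) base::which(which) else as.integer(which)
  structure(list(connectomes = set$connectomes[ii],
                 index = set$index[ii, , drop = FALSE]),
            class = "cs_connectome_set")
}
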