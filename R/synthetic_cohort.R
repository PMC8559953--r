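#' Study design for a synthetic connectome cohort
#'
#' Describes the hierarchical acquisition structure emulated by the cohort
#' generator: subjects, sessions per subject, subsamples per session
#' (odd/even splits of the directional measurements), measurement counts,
#' and the perturbation-simulation grid.
#'
#' @param n_subjects,n_sessions,n_subsamples counts (>= 1); `n_subsamples`
#'   must be 1 (full acquisition) or 2 (odd/even split).
#' @param n_volumes directional measurements per session (even when
#'   `n_subsamples == 2`).
#' @param n_b0 non-directional baseline measurements per session.
#' @param n_sims perturbed executions per sample (the unperturbed reference
#'   execution is additional).
#' @param pipelines subset of `c("det", "prob")`.
#' @param modes subset of `c("dense", "sparse")`.
#' @return an object of class `cs_design`.
#' @seealso [design_preset()] for the repeated-measures (25 x 2 x 2),
#'   cross-sectional (100 x 1 x 1) and smoke presets;
#'   [count_executions()] for the execution bookkeeping.
#' @export
study_design <- function(n_subjects, n_sessions, n_subsamples,
                         n_volumes = 128L, n_b0 = 9L, n_sims = 20L,
                         pipelines = c("det", "prob"),
                         modes = c("dense", "sparse")) {
  counts <- c(n_subjects, n_sessions, n_subsamples, n_volumes)
  if (any(!is.finite(counts)) || any(counts < 1) || n_b0 < 0 || n_sims < 0) {
    stop("invalid study design: counts must be >= 1 (n_b0, n_sims >= 0)")
  }
  if (!n_subsamples %in% c(1, 2)) {
    stop("n_subsamples must be 1 (full) or 2 (odd/even split)")
  }
  if (n_subsamples == 2 && n_volumes %% 2 != 0) {
    stop("odd/even subsampling requires an even n_volumes")
  }
  pipelines <- match.arg(pipelines, c("det", "prob"), several.ok = TRUE)
  modes <- match.arg(modes, c("dense", "sparse"), several.ok = TRUE)
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_sessions = as.integer(n_sessions),
         n_subsamples = as.integer(n_subsamples),
         n_volumes = as.integer(n_volumes), n_b0 = as.integer(n_b0),
         n_sims = as.integer(n_sims),
         pipelines = pipelines, modes = modes),
    class = "cs_design"
  )
}

#' Built-in study-design presets
#'
#' * `"repeated"`: 25 subjects x 2 sessions x 2 subsamples (100 samples),
#'   128 directional + 9 baseline volumes, 20 simulations;
#' * `"cross"`: 100 subjects x 1 session x 1 subsample, same volumes and
#'   simulation count;
#' * `"smoke"`: a down-scaled design (4 x 2 x 2, 24 + 3 volumes, 2 sims) for
#'   fast end-to-end runs.
#'
#' @param name preset name.
#' @return a [study_design()].
#' @export
design_preset <- function(name = c("repeated", "cross", "smoke")) {
  switch(match.arg(name),
    repeated = study_design(25, 2, 2, 128, 9, 20),
    cross    = study_design(100, 1, 1, 128, 9, 20),
    smoke    = study_design(4, 2, 2, 24, 3, 2)
  )
}

#' Number of samples in a design
#' @param design a [study_design()].
#' @return integer: subjects x sessions x subsamples.
#' @export
n_samples <- function(design) {
  design$n_subjects * design$n_sessions * design$n_subsamples
}

# Acquisition scheme shared by the whole cohort: n_volumes unit direction
# vectors plus n_b0 zero-direction baselines, and the 7-column signal design
# (intercept, direction components, pairwise products). Generic direction
# sets keep the design full rank.
make_scheme <- function(n_volumes, n_b0) {
  d <- matrix(stats::rnorm(n_volumes * 3), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  dirs <- rbind(matrix(0, n_b0, 3), d)
  b0 <- c(rep(TRUE, n_b0), rep(FALSE, n_volumes))
  X <- cbind(1, dirs,
             dirs[, 1] * dirs[, 2], dirs[, 1] * dirs[, 3],
             dirs[, 2] * dirs[, 3])
  colnames(X) <- c("b0", "dx", "dy", "dz", "dxy", "dxz", "dyz")
  list(directions = dirs, b0 = b0, X = X)
}

#' Generate a synthetic cohort with hierarchical variance structure
#'
#' Each subject carries a latent 6-dimensional node-factor matrix; sessions
#' add a session-specific bias field; each measurement volume adds i.i.d.
#' noise. A binary phenotype label is drawn through a logistic link on a
#' one-dimensional latent covariate embedded in the connectivity factors.
#' The whole cohort is fully determined by `seed`.
#'
#' @param design a [study_design()].
#' @param n_nodes parcellation size of the synthetic connectomes.
#' @param sigma_subject,sigma_session,sigma_subsample variance components
#'   (nonnegative): subject-level factor spread, session bias field spread,
#'   and per-volume measurement noise (the source of subsample differences).
#' @param assoc phenotype association strength: the log-odds slope of the
#'   label on the standardized latent covariate. `assoc = 0` makes labels
#'   independent of connectivity.
#' @param signal_scale how strongly the latent covariate is embedded in the
#'   node factors (hence how recoverable it is from the connectomes); the
#'   default, together with `assoc`, puts achievable classification
#'   accuracy in the 0.65-0.75 regime.
#' @param seed integer seed.
#' @return an object of class `cs_cohort` with fields `design`, `n_nodes`,
#'   `coords`, `scheme`, `subjects` (latent factors, covariate `z`, `label`),
#'   `samples` (manifest data frame), and `measurements` (nested
#'   subject/session/subsample list of measurement sets).
#' @export
generate_cohort <- function(design, n_nodes = 40L,
                            sigma_subject = 1.0, sigma_session = 0.3,
                            sigma_subsample = 0.1, assoc = 1.5,
                            signal_scale = 0.5, seed = 1L) {
  stopifnot(inherits(design, "cs_design"))
  if (n_nodes < 2) stop("invalid design: n_nodes must be >= 2")
  if (any(c(sigma_subject, sigma_session, sigma_subsample) < 0)) {
    stop("variance components must be nonnegative")
  }
  with_seed(derive_seed(seed, 101), {
    coords <- matrix(stats::runif(n_nodes * 3), ncol = 3)
    scheme <- make_scheme(design$n_volumes, design$n_b0)
    s0 <- stats::runif(n_nodes, 90, 110)
    F0 <- matrix(stats::rnorm(n_nodes * 6, sd = 1), n_nodes, 6)
    Wdir <- matrix(stats::rnorm(n_nodes * 6, sd = 1), n_nodes, 6)

    subjects <- lapply(seq_len(design$n_subjects), function(s) {
      z <- stats::rnorm(1)
      label <- stats::rbinom(1, 1, stats::plogis(assoc * z))
      Fs <- F0 + signal_scale * z * Wdir +
        sigma_subject * matrix(stats::rnorm(n_nodes * 6), n_nodes, 6)
      factors <- lapply(seq_len(design$n_sessions), function(e) {
        Fs + sigma_session * matrix(stats::rnorm(n_nodes * 6), n_nodes, 6)
      })
      latent <- pmax(tcrossprod(Fs), 0)
      diag(latent) <- 0
      list(z = z, label = label, factors = factors, latent_profile = latent)
    })

    measurements <- lapply(seq_len(design$n_subjects), function(s) {
      lapply(seq_len(design$n_sessions), function(e) {
        C <- rbind(s0, t(subjects[[s]]$factors[[e]]))
        Y <- scheme$X %*% C +
          sigma_subsample * matrix(stats::rnorm(nrow(scheme$X) * n_nodes),
                                   nrow(scheme$X), n_nodes)
        full <- list(Y = Y, X = scheme$X, b0 = scheme$b0,
                     directions = scheme$directions)
        if (design$n_subsamples == 2) split_subsamples(full) else list(full)
      })
    })

    samples <- expand.grid(subsample = seq_len(design$n_subsamples),
                           session = seq_len(design$n_sessions),
                           subject = seq_len(design$n_subjects))
    samples <- samples[, c("subject", "session", "subsample")]
    rownames(samples) <- NULL

    structure(
      list(design = design, n_nodes = as.integer(n_nodes), coords = coords,
           scheme = scheme, s0 = s0, subjects = subjects,
           samples = samples, measurements = measurements,
           params = list(sigma_subject = sigma_subject,
                         sigma_session = sigma_session,
                         sigma_subsample = sigma_subsample,
                         assoc = assoc, signal_scale = signal_scale,
                         seed = as.integer(seed))),
      class = "cs_cohort"
    )
  })
}

#' @export
print.cs_cohort <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "<cs_cohort> %d subjects x %d sessions x %d subsamples (%d samples), %d nodes\n",
    d$n_subjects, d$n_sessions, d$n_subsamples, n_samples(d), x$n_nodes))
  invisible(x)
}

#' Labels of a cohort, one per subject
#' @param cohort a [generate_cohort()] result.
#' @return integer vector of binary phenotype labels.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, function(s) as.integer(s$label), integer(1))
}

#' Split a session's measurements into odd/even subsamples
#'
#' Each subsample keeps every other directional measurement (alternating
#' indices) plus all baseline measurements, so that the two subsamples
#' partition the directional set and each represents a realistic complete
#' acquisition (e.g. 64 directional + 9 baseline = 73 measurements from a
#' 128-direction session).
#'
#' @param msmt a measurement set: list with matrix `Y` (measurements x
#'   nodes), design `X`, logical `b0`, and `directions`.
#' @return list of two measurement sets (odd, even).
#' @export
split_subsamples <- function(msmt) {
  stopifnot(is.list(msmt), is.matrix(msmt$Y), is.logical(msmt$b0))
  dir_idx <- which(!msmt$b0)
  if (length(dir_idx) %% 2 != 0) {
    stop("odd/even subsampling requires an even number of directional measurements")
  }
  take <- function(keep_dirs) {
    rows <- sort(c(which(msmt$b0), keep_dirs))
    list(Y = msmt$Y[rows, , drop = FALSE], X = msmt$X[rows, , drop = FALSE],
         b0 = msmt$b0[rows], directions = msmt$directions[rows, , drop = FALSE])
  }
  list(take(dir_idx[seq(1, length(dir_idx), by = 2)]),
       take(dir_idx[seq(2, length(dir_idx), by = 2)]))
}
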