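#' The discriminability statistic
#'
#' The probability, over all (anchor, within-class partner, cross-class
#' observation) triples, that the within-class distance is no larger than
#' the cross-class distance:
#' `D = Pr( d(g_ij, g_ij') <= d(g_i'j') )`, a rank-based test-retest
#' reliability statistic. Ties count as successes (the `<=` is literal), so
#' adding duplicate within-class observations never decreases `D`.
#'
#' @param x numeric matrix of observations (rows) by features, typically
#'   vectorized connectome upper triangles; or a precomputed [stats::dist]
#'   /distance matrix with `distance = "precomputed"`.
#' @param labels class labels, one per observation; >= 2 classes, every
#'   class >= 2 observations.
#' @param distance `"euclidean"` (default, on rows of `x`) or
#'   `"precomputed"`.
#' @return scalar in \[0, 1\].
#' @export
discriminability <- function(x, labels, distance = c("euclidean", "precomputed")) {
  distance <- match.arg(distance)
  D <- if (distance == "precomputed") as.matrix(x) else
    as.matrix(stats::dist(as.matrix(x)))
  labels <- as.vector(labels)
  n <- length(labels)
  stopifnot(nrow(D) == n)
  if (length(unique(labels)) < 2) stop("need >= 2 classes")
  if (min(table(labels)) < 2) {
    stop("insufficient replicates: every class needs >= 2 observations")
  }
  hits <- 0; total <- 0
  for (i in seq_len(n)) {
    within <- which(labels == labels[i]); within <- within[within != i]
    cross <- which(labels != labels[i])
    dw <- D[i, within]; dc <- D[i, cross]
    hits <- hits + sum(outer(dw, dc, `<=`))
    total <- total + length(dw) * length(dc)
  }
  hits / total
}

#' Permutation test for discriminability
#'
#' Permutes class labels within the stated exchangeability blocks,
#' recomputes the statistic, and returns
#' `p = (1 + #\{D_perm >= D_obs\}) / (1 + n_perm)`.
#'
#' @param x observations (or precomputed distances, see
#'   [discriminability()]).
#' @param labels class labels.
#' @param blocks optional exchangeability blocks: labels are permuted only
#'   within each block (e.g. session labels within subject); `NULL` permutes
#'   globally.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param distance passed to [discriminability()].
#' @return list with `p_value`, `statistic` (observed D), `perm` (the
#'   permuted statistics) and `n_perm`.
#' @export
permutation_test <- function(x, labels, blocks = NULL, n_perm = 1000L,
                             seed = 1L, distance = "euclidean") {
  stopifnot(n_perm >= 1)
  labels <- as.vector(labels)
  if (!is.null(blocks) && length(blocks) != length(labels)) {
    stop("design error: blocks incompatible with labels")
  }
  D <- if (distance == "precomputed") as.matrix(x) else
    as.matrix(stats::dist(as.matrix(x)))
  obs <- discriminability(D, labels, distance = "precomputed")
  perm <- with_seed(derive_seed(seed, 7L), {
    vapply(seq_len(n_perm), function(b) {
      pl <- permute_in_blocks(labels, blocks)
      tryCatch(discriminability(D, pl, distance = "precomputed"),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  perm <- perm[!is.na(perm)]
  list(p_value = (1 + sum(perm >= obs)) / (1 + length(perm)),
       statistic = obs, perm = perm, n_perm = length(perm))
}

permute_in_blocks <- function(labels, blocks) {
  if (is.null(blocks)) return(sample(labels))
  out <- labels
  for (b in split(seq_along(labels), blocks)) out[b] <- sample(labels[b])
  out
}

#' Run one discriminability hypothesis on a reconstructed cohort
#'
#' Implements the three class-based variability hypotheses:
#' * `H1` — subjects are distinct (class = subject ID); observations vary
#'   over the `comparison` level (`"session"`, `"subsample"`, or `"mca"`)
#'   with the remaining levels fixed, giving independent observation sets
#'   that are evaluated separately and aggregated;
#' * `H2` — sessions within a subject are distinct (class = session |
#'   subject); observations vary over subsamples (`comparison =
#'   "subsample"`) or MCA simulations at a fixed subsample (`"mca"`);
#'   evaluated per subject, aggregated across subjects;
#' * `H3` — subsamples are distinct (class = subsample | subject, session);
#'   observations are the MCA simulations, so the hypothesis cannot be
#'   tested on reference executions.
#'
#' The permutation test permutes labels within the hypothesis's
#' exchangeability block (globally for H1; within subject for H2; within
#' subject x session for H3), jointly across the independent sets, and
#' compares the aggregated statistic.
#'
#' The reported `chance` follows the 1/(number of classes) reporting
#' convention; because the rank-based statistic has an exchangeable null
#' centred at 0.5 regardless of class count, the empirical permutation-null
#' mean is reported alongside as `chance_empirical`, and the scaled score
#' uses it: `scaled = (D - chance_empirical) / (1 - chance_empirical)`
#' (pluggable via `scale_fun(D, chance, chance_empirical)`).
#'
#' @param set a [reconstruct_cohort()] result.
#' @param hypothesis `"H1"`, `"H2"`, or `"H3"`.
#' @param pipeline,mode which pipeline / instrumentation stratum to test.
#' @param comparison observation-selection rule; defaults to the headline
#'   comparison for each hypothesis (`H1`: session, `H2`:
#'   subsample, `H3`: mca).
#' @param use_reference use reference executions (`TRUE`) or perturbed
#'   simulations for the varied observations where applicable.
#' @param n_perm,seed permutation-test controls.
#' @param scale_fun scaled-score hook.
#' @return an object of class `cs_discrim`: statistic, chance,
#'   chance_empirical, scaled score, permutation p-value, and metadata
#'   (hypothesis, comparison, pipeline, mode, n_sets, n_perm).
#' @export
run_hypothesis <- function(set, hypothesis = c("H1", "H2", "H3"),
                           pipeline = "det", mode = "dense",
                           comparison = NULL, use_reference = NULL,
                           n_perm = 1000L, seed = 1L,
                           scale_fun = default_scale) {
  hypothesis <- match.arg(hypothesis)
  if (is.null(comparison)) {
    comparison <- switch(hypothesis, H1 = "session", H2 = "subsample",
                         H3 = "mca")
  }
  comparison <- match.arg(comparison, c("session", "subsample", "mca"))
  if (is.null(use_reference)) use_reference <- comparison != "mca"
  if (hypothesis == "H3" && comparison != "mca") {
    stop("unsupported design: H3 varies only over MCA simulations")
  }

  idx <- set$index
  in_stratum <- idx$pipeline == pipeline & idx$mode == mode
  take <- if (use_reference) idx$sim == 0 else idx$sim > 0
  sel <- which(in_stratum & take)
  if (!length(sel)) stop("unsupported design: no executions in this stratum")
  sub <- idx[sel, , drop = FALSE]
  feats <- t(vapply(set$connectomes[sel],
                    function(cn) upper_triangle(cn$weights),
                    numeric(length(upper_triangle(set$connectomes[[sel[1]]]$weights)))))

  spec <- switch(hypothesis,
    H1 = list(class = "subject",
              fix = setdiff(c("session", "subsample", "sim"),
                            c(comparison, if (comparison == "mca") "sim")),
              block = NULL),
    H2 = list(class = "session",
              fix = setdiff(c("subsample", "sim"),
                            c(comparison, if (comparison == "mca") "sim")),
              block = "subject"),
    H3 = list(class = "subsample", fix = character(0),
              block = c("subject", "session"))
  )
  # Observations vary over `comparison` (plus sims when comparison = "mca");
  # each combination of the fixed levels forms an independent set. For H2/H3
  # the subject (and session) enter the set key as exchangeability context.
  set_fields <- unique(c(spec$fix,
                         switch(hypothesis, H1 = character(0),
                                H2 = "subject", H3 = c("subject", "session"))))
  set_key <- if (length(set_fields)) {
    interaction(lapply(set_fields, function(f) sub[[f]]), drop = TRUE)
  } else {
    factor(rep("all", nrow(sub)))
  }

  sets <- list()
  for (g in split(seq_len(nrow(sub)), set_key)) {
    labs <- sub[[spec$class]][g]
    if (length(unique(labs)) < 2 || min(table(labs)) < 2) next
    blocks <- if (is.null(spec$block)) NULL else
      interaction(lapply(spec$block, function(f) sub[[f]][g]), drop = TRUE)
    sets[[length(sets) + 1L]] <- list(
      D = as.matrix(stats::dist(feats[g, , drop = FALSE])),
      labels = labs, blocks = blocks)
  }
  if (!length(sets)) {
    stop(sprintf(
      "unsupported design: no valid observation sets for %s/%s on this cohort%s",
      hypothesis, comparison,
      if (hypothesis == "H3" && use_reference)
        " (H3 cannot be tested on reference executions)" else ""))
  }

  stat_of <- function(label_list) {
    mean(vapply(seq_along(sets), function(k) {
      discriminability(sets[[k]]$D, label_list[[k]], distance = "precomputed")
    }, numeric(1)))
  }
  obs <- stat_of(lapply(sets, `[[`, "labels"))
  perm <- with_seed(derive_seed(seed, 13L), {
    vapply(seq_len(n_perm), function(b) {
      stat_of(lapply(sets, function(s) permute_in_blocks(s$labels, s$blocks)))
    }, numeric(1))
  })
  chance <- 1 / length(unique(sub[[spec$class]]))
  chance_emp <- mean(perm)
  structure(
    list(statistic = obs, chance = chance, chance_empirical = chance_emp,
         scaled = scale_fun(obs, chance, chance_emp),
         p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
         n_perm = as.integer(n_perm), n_sets = length(sets),
         hypothesis = hypothesis, comparison = comparison,
         pipeline = pipeline, mode = mode,
         use_reference = use_reference,
         note = paste("chance follows the 1/n_classes reporting convention;",
                      "the exchangeable permutation null centres near 0.5")),
    class = "cs_discrim"
  )
}

#' Default scaled-score hook
#'
#' Anchors the optimum at 1 while measuring exceedance over the empirical
#' permutation-null mean: `(D - chance_empirical)/(1 - chance_empirical)`.
#' The raw statistic is always reported alongside.
#'
#' @param d observed statistic.
#' @param chance 1/n_classes reporting convention (unused here).
#' @param chance_empirical empirical permutation-null mean.
#' @return scaled score (<= 1).
#' @export
default_scale <- function(d, chance, chance_empirical) {
  if (chance_empirical >= 1) return(NA_real_)
  (d - chance_empirical) / (1 - chance_empirical)
}

#' @export
print.cs_discrim <- function(x, ...) {
  cat(sprintf(
    "<cs_discrim> %s (%s, %s/%s%s): D = %.3f, chance = %.3g (empirical %.3f), scaled = %.3f, p = %.4g [%d sets, %d perms]\n",
    x$hypothesis, x$comparison, x$pipeline, x$mode,
    if (x$use_reference) ", reference" else ", MCA", x$statistic, x$chance,
    x$chance_empirical, x$scaled, x$p_value, x$n_sets, x$n_perm))
  invisible(x)
}

#' Paired cross-condition comparisons with multiple-comparison correction
#'
#' Wilcoxon signed-rank tests between every pair of conditions (paired,
#' equal-length statistic lists), with Benjamini-Hochberg correction across
#' the family. Condition pairs whose differences are all zero are returned
#' as a degenerate sentinel (`NA` p-value, no rejection) and excluded from
#' the correction family.
#'
#' @param stats named list of equal-length numeric vectors, one per
#'   condition, paired across conditions.
#' @param q BH false-discovery-rate level used for the `reject` flag.
#' @return data frame with columns `cond_a`, `cond_b`, `direction`
#'   (sign of the median difference `b - a`), `p`, `p_adj`, `reject`,
#'   `degenerate`.
#' @export
compare_conditions <- function(stats, q = 0.05) {
  stopifnot(is.list(stats), length(stats) >= 2, !is.null(names(stats)))
  lens <- lengths(stats)
  if (length(unique(lens)) != 1) stop("condition lists must be equal length")
  cmb <- utils::combn(names(stats), 2)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    a <- stats[[cmb[1, k]]]; b <- stats[[cmb[2, k]]]
    d <- b - a
    if (all(d == 0)) {
      data.frame(cond_a = cmb[1, k], cond_b = cmb[2, k], direction = 0,
                 p = NA_real_, degenerate = TRUE)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE,
                                                exact = FALSE))
      data.frame(cond_a = cmb[1, k], cond_b = cmb[2, k],
                 direction = sign(stats::median(d)),
                 p = wt$p.value, degenerate = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !out$degenerate
  out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$reject <- !is.na(out$p_adj) & out$p_adj < q
  out
}
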