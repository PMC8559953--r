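#' Normalized percent deviation between two connectomes
#'
#' The Frobenius-norm ratio `||A - B||_F / ||A||_F`, scaling the norm of the
#' difference between a (perturbed) graph and the reference execution by the
#' norm of the reference. Zero iff the graphs are identical; 1 when `B` is
#' the empty graph. `A` is always the reference side.
#'
#' @param A reference connectome (matrix or `cs_connectome`); must not be
#'   all zero.
#' @param B comparison connectome of the same shape.
#' @return nonnegative scalar.
#' @export
percent_deviation <- function(A, B) {
  A <- as_weights(A); B <- as_weights(B)
  if (!identical(dim(A), dim(B))) stop("connectome shapes differ")
  na <- sqrt(sum(A^2))
  if (na == 0) stop("undefined reference: all-zero reference connectome")
  sqrt(sum((A - B)^2)) / na
}

#' Significant decimal digits of repeated measurements
#'
#' For each element, `s' = -log10(sigma / |mu|)` with `mu` the mean and
#' `sigma` the n-1-denominator sample standard deviation across repeated
#' executions, clipped to \[0, 15.7\] (the 64-bit double-precision bound).
#' Degenerate cases: `sigma = 0` gives the 15.7 cap (perfectly stable);
#' `mu = 0` with `sigma > 0` gives 0 digits.
#'
#' @param samples numeric matrix with one row per execution (>= 2 rows) and
#'   one column per element, or a numeric vector of >= 2 repeated values.
#' @param cap upper bound on reportable digits (default 15.7).
#' @return numeric vector of per-element significant digits.
#' @export
significant_digits <- function(samples, cap = 15.7) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  if (nrow(samples) < 2) {
    stop("insufficient data: significant digits need >= 2 samples")
  }
  mu <- colMeans(samples)
  sigma <- apply(samples, 2, stats::sd)
  s <- ifelse(sigma == 0, cap,
              ifelse(mu == 0, 0, -log10(sigma / abs(mu))))
  pmin(pmax(s, 0), cap)
}

#' Pearson correlation between two connectomes
#'
#' Product-moment correlation over the vectorized strict upper triangles,
#' complementing percent deviation by comparing structure rather than
#' intensity.
#'
#' @param A,B connectomes of identical shape.
#' @return correlation in \[-1, 1\], or `NA` (with a warning) when either
#'   upper triangle has zero variance.
#' @export
pearson_correlation <- function(A, B) {
  a <- upper_triangle(as_weights(A)); b <- upper_triangle(as_weights(B))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance input: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

as_weights <- function(x) {
  if (inherits(x, "cs_connectome")) x$weights else as.matrix(x)
}

comparison_levels <- c("mca", "subsample", "session", "subject")

#' Grouped stability report over a cohort's connectomes
#'
#' Enumerates the comparison pairs of a given class and computes percent
#' deviation, Pearson correlation, and per-edge significant digits for each
#' group:
#' * `"mca"` — reference vs. each perturbed simulation of the same sample
#'   (same subject, session, subsample, pipeline, mode); digits across the
#'   simulation distribution;
#' * `"subsample"` — reference executions of the two subsamples of one
#'   session;
#' * `"session"` — reference executions of the same subject across
#'   sessions;
#' * `"subject"` — reference executions across subjects.
#'
#' Non-MCA classes compare reference executions within one pipeline/mode
#' stratum, removing tool-noise effects from the acquisition-level
#' comparisons; digits are computed over the complete distribution of
#' networks in each group. All upper-triangle entries (including structural
#' zeros) enter the per-edge digit summary unless `include_zero_edges` is
#' `FALSE`.
#'
#' @param set a [reconstruct_cohort()] result (or compatible list with
#'   `connectomes` and `index`).
#' @param class one of `"mca"`, `"subsample"`, `"session"`, `"subject"`.
#' @param include_zero_edges include edges absent everywhere in the digit
#'   summary?
#' @return an object of class `cs_stability`: list with `class`, `pairs`
#'   (data frame: group id, pair ids, `pdev`, `pearson`) and `digits`
#'   (data frame: group id, mean per-edge significant digits).
#' @export
group_stability <- function(set, class = comparison_levels,
                            include_zero_edges = TRUE) {
  class <- match.arg(class)
  idx <- set$index
  w <- lapply(set$connectomes, function(cn) cn$weights)

  strat <- interaction(idx$pipeline, idx$mode, drop = TRUE)
  pair_rows <- list(); digit_rows <- list()

  if (class == "mca") {
    groups <- split(seq_len(nrow(idx)),
                    interaction(idx$subject, idx$session, idx$subsample, strat,
                                drop = TRUE))
    for (g in groups) {
      ref <- g[idx$sim[g] == 0]
      sims <- g[idx$sim[g] > 0]
      if (length(ref) != 1 || length(sims) < 1) next
      gid <- group_id(idx[ref, ])
      for (s in sims) {
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          group = gid, a = ref, b = s,
          pdev = percent_deviation(w[[ref]], w[[s]]),
          pearson = suppressWarnings(pearson_correlation(w[[ref]], w[[s]])))
      }
      digit_rows[[length(digit_rows) + 1L]] <-
        data.frame(group = gid,
                   digits = edge_digits(w[sims], include_zero_edges))
    }
  } else {
    refs <- which(idx$sim == 0)
    vary <- switch(class, subsample = "subsample", session = "session",
                   subject = "subject")
    fixed <- switch(class,
                    subsample = c("subject", "session"),
                    session = "subject",
                    subject = character(0))
    key <- interaction(c(lapply(fixed, function(f) idx[[f]][refs]),
                         list(strat[refs])), drop = TRUE)
    groups <- split(refs, key)
    for (g in groups) {
      lev <- idx[[vary]][g]
      if (length(unique(lev)) < 2) next
      gid <- paste(class, group_id(idx[g[1], , drop = FALSE], fixed), sep = ":")
      cmb <- utils::combn(seq_along(g), 2)
      for (k in seq_len(ncol(cmb))) {
        a <- g[cmb[1, k]]; b <- g[cmb[2, k]]
        if (idx[[vary]][a] == idx[[vary]][b]) next
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          group = gid, a = a, b = b,
          pdev = percent_deviation(w[[a]], w[[b]]),
          pearson = suppressWarnings(pearson_correlation(w[[a]], w[[b]])))
      }
      digit_rows[[length(digit_rows) + 1L]] <-
        data.frame(group = gid, digits = edge_digits(w[g], include_zero_edges))
    }
  }

  if (!length(pair_rows)) {
    stop(sprintf("empty class: no valid '%s' pairs in this cohort", class))
  }
  structure(list(class = class,
                 pairs = do.call(rbind, pair_rows),
                 digits = do.call(rbind, digit_rows)),
            class = "cs_stability")
}

group_id <- function(row, fields = c("subject", "session", "subsample",
                                     "pipeline", "mode")) {
  fields <- c(fields, "pipeline", "mode")
  fields <- intersect(unique(fields), names(row))
  paste(vapply(fields, function(f) paste0(f, row[[f]][1]), character(1)),
        collapse = ".")
}

# Mean per-edge significant digits over a group of weight matrices.
edge_digits <- function(wlist, include_zero_edges = TRUE) {
  if (length(wlist) < 2) return(NA_real_) # digits need >= 2 networks
  mat <- do.call(rbind, lapply(wlist, upper_triangle))
  d <- significant_digits(mat)
  if (!include_zero_edges) {
    keep <- colSums(mat != 0) > 0
    if (!any(keep)) return(NA_real_)
    d <- d[keep]
  }
  mean(d)
}

#' @export
print.cs_stability <- function(x, ...) {
  cat(sprintf("<cs_stability> class = %s: %d pairs, median %%Dev = %.3g, mean edge digits = %.2f\n",
              x$class, nrow(x$pairs), stats::median(x$pairs$pdev),
              mean(x$digits$digits, na.rm = TRUE)))
  invisible(x)
}

#' Write a stability report to CSV / JSON
#'
#' @param report a [group_stability()] result.
#' @param csv,json optional output paths (pair rows to CSV; summary to JSON).
#' @return invisibly, the summary list.
#' @export
write_stability <- function(report, csv = NULL, json = NULL) {
  smry <- list(class = report$class,
               n_pairs = nrow(report$pairs),
               median_pdev = stats::median(report$pairs$pdev),
               median_pearson = stats::median(report$pairs$pearson, na.rm = TRUE),
               mean_edge_digits = mean(report$digits$digits, na.rm = TRUE))
  if (!is.null(csv)) {
    utils::write.csv(report$pairs, csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(smry, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(smry)
}
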