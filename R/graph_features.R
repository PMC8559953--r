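#' Convert a weight matrix to an igraph graph
#'
#' @param W symmetric nonnegative weight matrix (or `cs_connectome`).
#' @return an undirected weighted igraph object (no self loops).
#' @keywords internal
as_graph <- function(W) {
  W <- as_weights(W)
  diag(W) <- 0
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
}

#' Graph-theoretic features of a connectome
#'
#' Weighted-graph definitions throughout; path-based measures use
#' inverse-weight edge lengths (`length = 1/weight`, the standard weighted
#' connectome convention). Computed features:
#'
#' * univariate: edge count, mean (Barrat) clustering coefficient, global
#'   efficiency, modularity of the largest connected component (seeded
#'   greedy modularity maximization), strength assortativity, and mean
#'   shortest-path length over reachable pairs;
#' * nodewise: binary degree, Barrat local clustering, betweenness
#'   centrality (inverse-weight lengths);
#' * edgewise: positive edge weights and connection lengths (Euclidean
#'   distance between node coordinates, a geometric proxy for streamline
#'   length).
#'
#' Disconnected graphs are handled naturally: unreachable pairs contribute
#' zero efficiency and are excluded from the mean path length. Degenerate
#' regular graphs have undefined (NaN) assortativity. An empty graph yields
#' sentinel values (0 edges, NA where undefined).
#'
#' @param W connectome weight matrix or `cs_connectome`.
#' @param coords optional n x 3 node coordinates for connection lengths.
#' @param sets which feature blocks to compute.
#' @param community_seed seed for the community-detection step.
#' @return list with elements `univariate` (named numeric), `nodewise`
#'   (named list of per-node vectors) and `edgewise` (named list).
#' @export
compute_features <- function(W, coords = NULL,
                             sets = c("univariate", "nodewise", "edgewise"),
                             community_seed = 42L) {
  W <- as_weights(W)
  check_connectome(W)
  n <- nrow(W)
  g <- as_graph(W)
  len <- 1 / igraph::E(g)$weight
  out <- list()

  dmat <- if (igraph::ecount(g) > 0) {
    igraph::distances(g, weights = len)
  } else {
    matrix(Inf, n, n)
  }
  diag(dmat) <- Inf # exclude self pairs uniformly
  finite_d <- dmat[upper.tri(dmat)][is.finite(dmat[upper.tri(dmat)])]

  if ("univariate" %in% sets) {
    ec <- sum(upper_triangle(W) > 0)
    clust <- barrat_clustering(W)
    eff <- if (n < 2) NA_real_ else {
      dv <- dmat[upper.tri(dmat)]
      mean(ifelse(is.finite(dv), 1 / dv, 0))
    }
    mod <- modularity_lcc(g, community_seed)
    assort <- strength_assortativity(W)
    mpl <- if (length(finite_d)) mean(finite_d) else NA_real_
    out$univariate <- c(edge_count = ec,
                        mean_clustering = mean_defined(clust),
                        global_efficiency = eff,
                        modularity = mod,
                        assortativity = assort,
                        mean_path_length = mpl)
  }
  if ("nodewise" %in% sets) {
    out$nodewise <- list(
      degree = rowSums(W > 0),
      clustering = ifelse(is.nan(barrat_clustering(W)), 0,
                          barrat_clustering(W)),
      betweenness = if (igraph::ecount(g) > 0) {
        igraph::betweenness(g, weights = len)
      } else {
        rep(0, n)
      })
  }
  if ("edgewise" %in% sets) {
    keep <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    ew <- list(weight = W[upper.tri(W) & W > 0])
    if (!is.null(coords)) {
      ew$connection_length <- sqrt(rowSums(
        (coords[keep[, 1], , drop = FALSE] -
           coords[keep[, 2], , drop = FALSE])^2))
    }
    out$edgewise <- ew
  }
  out
}

check_connectome <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (any(!is.finite(W)) || any(W < 0)) stop("invalid connectome weights")
  if (max(abs(W - t(W))) > 1e-8 * max(1, max(abs(W)))) {
    stop("connectome must be symmetric")
  }
  invisible(W)
}

mean_defined <- function(x) {
  x <- x[!is.nan(x) & !is.na(x)]
  if (!length(x)) return(0)
  mean(x)
}

# Barrat weighted local clustering: for node i with strength s_i and binary
# degree k_i, C_i = 1/(s_i (k_i - 1)) * sum_{j,h} (w_ij + w_ih)/2 * a_ij a_ih a_jh.
# NaN for nodes of degree < 2.
barrat_clustering <- function(W) {
  A <- (W > 0) * 1
  n <- nrow(W)
  s <- rowSums(W)
  k <- rowSums(A)
  out <- rep(NaN, n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    nb <- which(A[i, ] > 0)
    tot <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a == b) next
        j <- nb[a]; h <- nb[b]
        if (A[j, h] > 0) tot <- tot + (W[i, j] + W[i, h]) / 2
      }
    }
    out[i] <- tot / (s[i] * (k[i] - 1)) # sum over ordered neighbour pairs
  }
  out
}

# Strength (weighted-degree) assortativity: Pearson correlation of endpoint
# strengths over edges, each undirected edge contributing both orientations.
strength_assortativity <- function(W) {
  s <- rowSums(W)
  e <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(e) < 2) return(NA_real_)
  a <- c(s[e[, 1]], s[e[, 2]])
  b <- c(s[e[, 2]], s[e[, 1]])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NaN)
  stats::cor(a, b)
}

# Modularity of the largest connected component under seeded greedy
# modularity maximization.
modularity_lcc <- function(g, seed = 42L) {
  if (igraph::ecount(g) == 0) return(NA_real_)
  comp <- igraph::components(g)
  lcc <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  with_seed(seed, {
    cl <- igraph::cluster_fast_greedy(lcc, weights = igraph::E(lcc)$weight)
    igraph::modularity(lcc, igraph::membership(cl),
                       weights = igraph::E(lcc)$weight)
  })
}

#' Partition of the largest connected component (for oracle checks)
#' @param W weight matrix.
#' @param community_seed seed for community detection.
#' @return list with `membership` and the node indices of the component.
#' @export
community_partition <- function(W, community_seed = 42L) {
  g <- as_graph(W)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  lcc <- igraph::induced_subgraph(g, keep)
  memb <- with_seed(community_seed, {
    igraph::membership(igraph::cluster_fast_greedy(
      lcc, weights = igraph::E(lcc)$weight))
  })
  list(membership = as.integer(memb), nodes = keep,
       weights = igraph::as_adjacency_matrix(lcc, attr = "weight",
                                             sparse = FALSE))
}

#' Z-score false-positive rate of univariate features under perturbation
#'
#' Each sample's feature value is Z-scored against its within-subject
#' perturbation distribution; the proportion of "classically significant"
#' scores (two-sided p < 0.05, i.e. |Z| >= 1.96) is pooled across subjects,
#' deliberately without multiple-comparison correction. Subjects with zero
#' within-subject variance are flagged perfectly stable and excluded from
#' the proportion.
#'
#' @param values_by_subject list of per-subject numeric vectors (feature
#'   values across >= 2 perturbed executions).
#' @param alpha two-sided significance level (default 0.05).
#' @return list with `fpr` (pooled proportion; `NA` if every subject is
#'   perfectly stable), `n_stable` (excluded subjects), `n_values`.
#' @export
univariate_zscore_fpr <- function(values_by_subject, alpha = 0.05) {
  stopifnot(is.list(values_by_subject))
  zcrit <- stats::qnorm(1 - alpha / 2)
  flags <- integer(0); n_stable <- 0L
  for (v in values_by_subject) {
    if (length(v) < 2) stop("need >= 2 perturbed values per subject")
    s <- stats::sd(v)
    if (s == 0) { n_stable <- n_stable + 1L; next }
    z <- (v - mean(v)) / s
    flags <- c(flags, as.integer(abs(z) >= zcrit))
  }
  list(fpr = if (length(flags)) mean(flags) else NA_real_,
       n_stable = n_stable, n_values = length(flags))
}

#' Evaluation grid for feature CDFs
#'
#' The fixed range over which cumulative distributions are evaluated:
#' from 0 to the 99.5th percentile of the feature over the reference
#' cohort, on `n` points.
#'
#' @param reference_values pooled feature values of the reference cohort.
#' @param n grid size (default 100).
#' @return numeric grid.
#' @export
feature_grid <- function(reference_values, n = 100L) {
  hi <- stats::quantile(reference_values, 0.995, names = FALSE)
  if (!is.finite(hi) || hi <= 0) hi <- max(reference_values, 1e-12)
  seq(0, hi, length.out = n)
}

#' Moment-level stability of multivariate feature distributions
#'
#' For each subject's nodewise/edgewise feature distribution observed across
#' perturbed simulations: evaluates the empirical CDF on a fixed grid
#' (pooled over simulations, then averaged across subjects with standard
#' error), and computes the five moments (sum, mean, variance, skew, excess
#' kurtosis) per simulation, whose significant digits across simulations
#' quantify moment stability (aggregated across subjects).
#'
#' @param values_by_subject list over subjects; each element a matrix with
#'   one row per simulation (>= 2) and one column per node/edge value, or a
#'   list of per-simulation numeric vectors of a common length.
#' @param grid CDF evaluation grid; defaults to [feature_grid()] on the
#'   pooled values.
#' @return an object of class `cs_moments`: list with `digits` (data frame
#'   subject x moment), `digit_summary` (median digits per moment across
#'   subjects), `moments` (per subject x sim x moment values), and `cdf`
#'   (grid, per-subject curves, across-subject mean and standard error).
#' @export
multivariate_stability <- function(values_by_subject, grid = NULL) {
  stopifnot(is.list(values_by_subject), length(values_by_subject) >= 1)
  values_by_subject <- lapply(values_by_subject, function(v) {
    if (is.list(v)) v <- do.call(rbind, v)
    if (is.null(dim(v))) stop("each subject needs a sims x values matrix")
    if (nrow(v) < 2) stop("need >= 2 simulations per subject")
    v
  })
  ncols <- vapply(values_by_subject, ncol, integer(1))
  if (length(unique(ncols)) != 1) {
    stop("shape error: inconsistent value counts across subjects")
  }
  if (is.null(grid)) {
    grid <- feature_grid(unlist(values_by_subject))
  }

  moment_names <- c("sum", "mean", "variance", "skew", "kurtosis")
  mom_rows <- list(); dig_rows <- list(); cdfs <- list()
  for (s in seq_along(values_by_subject)) {
    v <- values_by_subject[[s]]
    m <- t(apply(v, 1, five_moments))
    colnames(m) <- moment_names
    mom_rows[[s]] <- data.frame(subject = s, sim = seq_len(nrow(v)), m,
                                row.names = NULL)
    dig_rows[[s]] <- data.frame(subject = s, moment = moment_names,
                                digits = significant_digits(m),
                                row.names = NULL)
    pooled <- as.vector(v)
    cdfs[[s]] <- stats::ecdf(pooled)(grid)
  }
  cdf_mat <- do.call(rbind, cdfs)
  digits <- do.call(rbind, dig_rows)
  smry <- stats::aggregate(digits ~ moment, data = digits, FUN = stats::median)
  structure(
    list(digits = digits,
         digit_summary = stats::setNames(smry$digits, smry$moment),
         moments = do.call(rbind, mom_rows),
         cdf = list(grid = grid, per_subject = cdf_mat,
                    mean = colMeans(cdf_mat),
                    se = if (nrow(cdf_mat) < 2) rep(0, ncol(cdf_mat)) else
                      apply(cdf_mat, 2, stats::sd) / sqrt(nrow(cdf_mat)))),
    class = "cs_moments"
  )
}

#' @export
print.cs_moments <- function(x, ...) {
  cat("<cs_moments> median significant digits per moment:\n")
  print(round(x$digit_summary, 2))
  invisible(x)
}

# sum, mean, variance (n-1), skew (g1), excess kurtosis (g2).
five_moments <- function(x) {
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  sk <- if (m2 == 0) 0 else mean(d^3) / m2^1.5
  ku <- if (m2 == 0) 0 else mean(d^4) / m2^2 - 3
  c(sum = sum(x), mean = mu, variance = stats::var(x), skew = sk,
    kurtosis = ku)
}
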