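test_that("closed-form anchors: complete graph and star", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  f <- compute_features(K4)$univariate
  expect_equal(unname(f["edge_count"]), 6)
  expect_equal(unname(f["mean_clustering"]), 1)
  expect_equal(unname(f["global_efficiency"]), 1)
  expect_equal(unname(f["mean_path_length"]), 1)

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 1; star[2:4, 1] <- 1
  nd <- compute_features(star)$nodewise
  expect_equal(nd$betweenness, c(3, 0, 0, 0)) # 3 leaf pairs through centre
  expect_equal(nd$degree, c(3, 1, 1, 1))
  expect_equal(nd$clustering, c(0, 0, 0, 0))  # degree<2 nodes report 0
})

test_that("degree distribution satisfies the handshake identity", {
  for (s in 1:5) {
    W <- random_connectome(9, density = 0.5, seed = s)
    f <- compute_features(W)
    expect_equal(sum(f$nodewise$degree), 2 * unname(f$univariate["edge_count"]))
  }
})

test_that("features equal first-principles oracles on small graphs", {
  cases <- c(lapply(1:8, function(s) random_connectome(7, 0.5, seed = s)),
             lapply(9:12, function(s) random_connectome(5, 0.35, seed = s)),
             list({ # disconnected: two components
               W <- matrix(0, 6, 6)
               W[1, 2] <- W[2, 1] <- 1.5; W[2, 3] <- W[3, 2] <- 0.5
               W[1, 3] <- W[3, 1] <- 0.2; W[4, 5] <- W[5, 4] <- 2
               W
             }))
  for (W in cases) {
    f <- compute_features(W, coords = matrix(seq_len(3 * nrow(W)), ncol = 3))
    expect_equal(unname(f$univariate["global_efficiency"]),
                 oracle_global_efficiency(W))
    expect_equal(unname(f$univariate["mean_path_length"]),
                 oracle_mean_path_length(W))
    expect_equal(unname(f$univariate["assortativity"]),
                 oracle_assortativity(W), tolerance = 1e-12)
    expect_equal(f$nodewise$betweenness, oracle_betweenness(W),
                 tolerance = 1e-10)
    bar <- oracle_barrat(W)
    expect_equal(f$nodewise$clustering, ifelse(is.nan(bar), 0, bar))
    expect_equal(unname(f$univariate["mean_clustering"]),
                 mean(bar[!is.nan(bar)]))
    # modularity: the reported Q equals the first-principles Q of the
    # partition found on the largest connected component
    part <- community_partition(W)
    expect_equal(unname(f$univariate["modularity"]),
                 oracle_modularity(part$weights, part$membership))
    # edgewise connection lengths match direct coordinate geometry
    idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    co <- matrix(seq_len(3 * nrow(W)), ncol = 3)
    expect_equal(f$edgewise$connection_length,
                 sqrt(rowSums((co[idx[, 1], ] - co[idx[, 2], ])^2)))
  }
})

test_that("degenerate graphs return sentinels, invalid input errors", {
  empty <- matrix(0, 4, 4)
  f <- compute_features(empty)$univariate
  expect_equal(unname(f["edge_count"]), 0)
  expect_equal(unname(f["mean_clustering"]), 0)
  expect_true(is.na(f["modularity"]))
  expect_true(is.na(f["mean_path_length"]))
  expect_error(compute_features(matrix(-1, 2, 2)), "invalid")
  expect_error(compute_features(matrix(rnorm(9), 3)), "symmetric|invalid")
})

test_that("z-score false-positive rate: stable, calibrated, bounded", {
  # all-identical values: flagged stable, excluded
  out <- univariate_zscore_fpr(list(rep(1, 10), rep(2, 5)))
  expect_true(is.na(out$fpr))
  expect_equal(out$n_stable, 2)

  # standard-normal draws: pooled FPR near 0.05
  set.seed(8)
  vals <- lapply(1:20, function(i) rnorm(500))
  out2 <- univariate_zscore_fpr(vals)
  se <- sqrt(0.05 * 0.95 / out2$n_values)
  expect_lt(abs(out2$fpr - 0.05), 3 * se + 0.005)

  # two-point distribution: |Z| -> 1, never significant
  out3 <- univariate_zscore_fpr(list(rep(c(0, 1), 50)))
  expect_equal(out3$fpr, 0)
  expect_error(univariate_zscore_fpr(list(1)), ">= 2")
})

test_that("moment stability: caps, identities, and order invariance", {
  # identical simulations -> every moment at the digit cap
  v <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 3, byrow = TRUE)
  ms <- multivariate_stability(list(v, v))
  expect_true(all(ms$digits$digits == 15.7))

  # handshake identity through the moment pipeline: sum(degree) = 2 edges
  W <- random_connectome(8, seed = 3)
  deg <- compute_features(W)$nodewise$degree
  m <- multivariate_stability(list(rbind(deg, deg)))
  expect_equal(unname(m$moments$sum[1]),
               2 * unname(compute_features(W)$univariate["edge_count"]))

  # CDF is monotone in [0, 1]; single-subject SE band contains pooled CDF
  set.seed(5)
  sims <- matrix(abs(rnorm(60)), nrow = 6)
  one <- multivariate_stability(list(sims))
  expect_true(all(diff(one$cdf$mean) >= 0))
  expect_true(all(one$cdf$mean >= 0 & one$cdf$mean <= 1))
  pooled <- stats::ecdf(as.vector(sims))(one$cdf$grid)
  expect_true(all(abs(one$cdf$mean - pooled) <= one$cdf$se + 1e-12))

  # digits invariant to simulation order
  two <- multivariate_stability(list(sims, sims[sample(6), ] * 1.1))
  reord <- multivariate_stability(list(sims[6:1, ], (sims[sample(6), ] * 1.1)))
  expect_equal(two$digit_summary, reord$digit_summary)
  expect_error(multivariate_stability(list(sims, sims[, 1:3])), "shape")
  expect_error(multivariate_stability(list(sims[1, , drop = FALSE])),
               ">= 2 simulations")
})

test_that("perturbed cohort feature moments lose digits as noise grows", {
  # moment digits must respond to the virtual precision: coarser noise
  # (smaller t) erodes more digits of the degree-distribution moments
  co <- tiny_cohort(13, design = tiny_design(n_subjects = 2, n_sessions = 1,
                                             n_subsamples = 1, n_sims = 4))
  digits_at <- function(t) {
    set <- reconstruct_cohort(co, t = t, base_seed = 3)
    sel <- which(set$index$sim > 0)
    by_subj <- split(sel, set$index$subject[sel])
    vals <- lapply(by_subj, function(ii) {
      do.call(rbind, lapply(ii, function(i) {
        unname(compute_features(set$connectomes[[i]])$nodewise$clustering)
      }))
    })
    stats::median(multivariate_stability(vals)$digits$digits)
  }
  expect_gt(digits_at(52), digits_at(20))
})
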