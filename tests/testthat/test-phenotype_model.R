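test_that("select_components follows the explained-variance rule", {
  set.seed(2)
  # one dominant direction (~99% of variance) -> 1 component
  u <- rnorm(60)
  dom <- cbind(10 * u, 10 * u + rnorm(60, 0, 0.1), rnorm(60, 0, 0.3))
  folds <- stratified_folds(rep(0:1, 30), 5, seed = 1)
  expect_equal(select_components(dom, folds), 1)

  # isotropic 10-dimensional data: with near-equal eigenvalues the top 9
  # sorted components explain just over 90%, so the equal-eigenvalue
  # closed form ceiling(0.9 * 10) = 9 applies (large n keeps the sample
  # eigenvalue spread small)
  iso <- matrix(rnorm(400 * 10), 400, 10)
  folds_iso <- stratified_folds(rep(0:1, 200), 5, seed = 1)
  expect_equal(select_components(iso, folds_iso), 9)

  # rank-deficient input falls back to full rank with a warning
  expect_warning(nc <- select_components(matrix(1, 20, 4) ,
                                         stratified_folds(rep(0:1, 10), 2),
                                         threshold = 0.9),
                 "full rank")
  expect_true(nc >= 1)
})

test_that("classification anchors: separable data, LOO folds, determinism", {
  set.seed(6)
  n <- 40
  labels <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6)
  x[labels == 1, 1] <- x[labels == 1, 1] + 25 # perfectly separable
  run <- classify_cohort(x, labels, k = 5, seed = 3)
  expect_equal(run$accuracy, 1.0)
  expect_equal(run$f1, 1.0)
  expect_true(run$explained_variance > 0 && run$explained_variance <= 1)

  loo <- classify_cohort(x, labels, k = n, seed = 3)
  expect_true(all(lengths(lapply(loo$per_fold, `[[`, "test")) == 1))

  again <- classify_cohort(x, labels, k = 5, seed = 3)
  expect_identical(run$predictions, again$predictions)
  expect_equal(run$accuracy, again$accuracy)
  expect_error(classify_cohort(x, rep(0, n), k = 5), "both classes")
})

test_that("no information leaks from test folds into the fitted model", {
  set.seed(10)
  labels <- rep(0:1, each = 15)
  x <- matrix(rnorm(30 * 8), 30, 8)
  x[labels == 1, 2] <- x[labels == 1, 2] + 2
  base <- classify_cohort(x, labels, k = 5, seed = 2, n_components = 4)
  fold1 <- base$per_fold[[1]]
  # corrupt the test rows of fold 1; the model fit on that fold's training
  # rows must be unchanged (identical coefficients). The component count is
  # pinned because its selection rule legitimately averages over all folds'
  # training sets, which include these rows for other folds.
  x2 <- x
  x2[fold1$test, ] <- matrix(rnorm(length(fold1$test) * 8) * 50,
                             length(fold1$test), 8)
  shuffled <- classify_cohort(x2, labels, k = 5, seed = 2, n_components = 4)
  expect_equal(shuffled$per_fold[[1]]$beta, fold1$beta)
})

test_that("zero phenotype association gives chance-level accuracy", {
  set.seed(21)
  accs <- vapply(1:12, function(r) {
    labels <- rep(0:1, each = 20)[sample(40)]
    x <- matrix(rnorm(40 * 10), 40, 10)
    classify_cohort(x, labels, k = 5, seed = r)$accuracy
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("resampled performance: degenerate and perturbed envelopes", {
  set.seed(12)
  n <- 24
  labels <- rep(0:1, each = n / 2)
  ref <- matrix(rnorm(n * 6), n, 6)
  ref[labels == 1, 1] <- ref[labels == 1, 1] + 3

  # zero-variance perturbations: every repeat identical to the reference
  x_by <- lapply(seq_len(n), function(i) rbind(ref[i, ], ref[i, ], ref[i, ]))
  rp <- resampled_performance(x_by, ref, labels, k = 4, n_repeats = 5,
                              seed = 2)
  expect_true(all(rp$runs$accuracy == rp$reference$accuracy))
  expect_true(all(rp$runs$f1 == rp$reference$f1))
  expect_equal(unname(rp$summary$accuracy["min"]),
               unname(rp$summary$accuracy["max"]))

  # real perturbations: nonzero spread, reference within a sane range
  x_by2 <- lapply(seq_len(n), function(i) {
    sweep(matrix(rnorm(5 * 6, 0, 0.8), 5, 6), 2, ref[i, ], `+`)
  })
  rp2 <- resampled_performance(x_by2, ref, labels, k = 4, n_repeats = 8,
                               seed = 3)
  expect_gt(rp2$summary$accuracy["max"], rp2$summary$accuracy["min"])
  expect_true(all(rp2$runs$accuracy >= 0 & rp2$runs$accuracy <= 1))
  # metrics are reproducible under identical seeds
  rp3 <- resampled_performance(x_by2, ref, labels, k = 4, n_repeats = 8,
                               seed = 3)
  expect_identical(rp2$runs, rp3$runs)
})

test_that("cohort-driven resampling responds to perturbation spread", {
  co <- tiny_cohort(19, design = tiny_design(n_subjects = 6, n_sessions = 1,
                                             n_subsamples = 1, n_sims = 2))
  set <- reconstruct_cohort(co, base_seed = 4)
  idx <- set$index
  subj <- sort(unique(idx$subject))
  pick <- function(s, sims) which(idx$subject == s & idx$session == 1 &
                                    idx$subsample == 1 &
                                    (if (sims) idx$sim > 0 else idx$sim == 0))
  xr <- t(vapply(subj, function(s) {
    upper_triangle(set$connectomes[[pick(s, FALSE)[1]]]$weights)
  }, numeric(28)))
  xs <- lapply(subj, function(s) {
    do.call(rbind, lapply(pick(s, TRUE), function(i) {
      upper_triangle(set$connectomes[[i]]$weights)
    }))
  })
  # 6 subjects cannot be classified meaningfully, but the plumbing must
  # hold: ulp-scale perturbations leave every repeat at the reference run
  rp <- resampled_performance(xs, xr, rep(c(0, 1), 3), k = 2, n_repeats = 3,
                              seed = 5)
  expect_equal(nrow(rp$runs), 3)
  expect_true(all(abs(rp$runs$explained_variance -
                        rp$reference$explained_variance) < 1e-6))
})
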