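test_that("study designs validate and count samples/executions correctly", {
  expect_equal(n_samples(design_preset("repeated")), 100)
  expect_equal(n_samples(design_preset("cross")), 100)
  expect_equal(count_executions(design_preset("repeated")), 8400)
  expect_equal(count_executions(design_preset("cross")), 8400)
  d1 <- study_design(1, 1, 1, 4, 0, 0 + 1, pipelines = "det", modes = "dense")
  expect_equal(n_samples(d1), 1)
  expect_error(study_design(0, 1, 1), "invalid study design")
  expect_error(study_design(2, 1, 3), "n_subsamples")
  expect_error(study_design(2, 1, 2, n_volumes = 7), "even")
  expect_error(generate_cohort(tiny_design(), sigma_session = -1),
               "nonnegative")
})

test_that("odd/even subsampling partitions directional measurements", {
  co <- generate_cohort(study_design(1, 1, 1, 128, 9, 1), n_nodes = 4,
                        seed = 1)
  full <- co$measurements[[1]][[1]][[1]]
  halves <- split_subsamples(full)
  expect_equal(nrow(halves[[1]]$Y), 73) # 64 directional + 9 baseline
  expect_equal(nrow(halves[[2]]$Y), 73)
  expect_equal(sum(halves[[1]]$b0), 9)

  # tiny case: two directional volumes, no baselines
  co2 <- generate_cohort(study_design(1, 1, 1, 2, 0, 1), n_nodes = 4, seed = 1)
  h2 <- split_subsamples(co2$measurements[[1]][[1]][[1]])
  expect_equal(nrow(h2[[1]]$Y), 1)
  expect_equal(nrow(h2[[2]]$Y), 1)

  # partition property over several even sizes: disjoint and exhaustive
  for (nv in c(4, 10, 64)) {
    coN <- generate_cohort(study_design(1, 1, 1, nv, 2, 1), n_nodes = 4,
                           seed = 2)
    f <- coN$measurements[[1]][[1]][[1]]
    hs <- split_subsamples(f)
    d1 <- hs[[1]]$directions[!hs[[1]]$b0, , drop = FALSE]
    d2 <- hs[[2]]$directions[!hs[[2]]$b0, , drop = FALSE]
    alldir <- f$directions[!f$b0, , drop = FALSE]
    expect_equal(nrow(d1) + nrow(d2), nv)
    expect_equal(dim(rbind(d1, d2)), dim(alldir))
    recomb <- rbind(d1, d2)
    expect_true(all(apply(alldir, 1, function(r) {
      any(colSums(abs(t(recomb) - r)) < 1e-12)
    })))
  }
  bad <- co2$measurements[[1]][[1]][[1]]
  bad$b0 <- c(TRUE, FALSE) # one directional row left
  expect_error(split_subsamples(bad), "even")
})

test_that("cohorts are seed-deterministic with the preset manifest shape", {
  a <- tiny_cohort(5); b <- tiny_cohort(5)
  expect_identical(a$measurements, b$measurements)
  expect_identical(cohort_labels(a), cohort_labels(b))
  rep_d <- design_preset("repeated")
  co <- generate_cohort(rep_d, n_nodes = 4, seed = 1)
  expect_equal(nrow(co$samples), 100)
  expect_equal(unique(table(co$samples$subject)), 4L)
})

test_that("zero session/subsample variance collapses a subject's samples", {
  d <- tiny_design(n_subjects = 1, n_sims = 0)
  co <- generate_cohort(d, n_nodes = 6, sigma_session = 0,
                        sigma_subsample = 0, seed = 3)
  off <- mca_profile(density = "off")
  refs <- lapply(seq_len(nrow(co$samples)), function(i) {
    m <- co$measurements[[co$samples$subject[i]]][[co$samples$session[i]]][[co$samples$subsample[i]]]
    reconstruct_connectome(m, "det", off, mca_rng(1))
  })
  expect_length(refs, 4)
  for (i in 2:4) {
    expect_lt(percent_deviation(refs[[1]], refs[[i]]), 1e-6)
  }
})

test_that("reconstruction is reference-reproducible and structurally valid", {
  co <- tiny_cohort(9, design = tiny_design(n_subjects = 1, n_sessions = 1))
  m <- co$measurements[[1]][[1]][[1]]
  off <- mca_profile(density = "off")
  for (pl in c("det", "prob")) {
    r1 <- reconstruct_connectome(m, pl, off, mca_rng(1))
    r2 <- reconstruct_connectome(m, pl, off, mca_rng(99))
    expect_identical(r1$weights, r2$weights) # bit-identical reference
    prof <- mca_profile(t = 52, mode = "rr", density = "dense", seed = 2)
    sims <- lapply(1:6, function(k) {
      reconstruct_connectome(m, pl, prof, mca_rng(derive_seed(2, k)))
    })
    for (s in sims) {
      W <- s$weights
      expect_true(all(is.finite(W)) && all(W >= 0))
      expect_identical(W, t(W))
      expect_true(all(diag(W) == 0))
    }
    spread <- apply(do.call(rbind, lapply(sims, function(s)
      upper_triangle(s$weights))), 2, sd)
    expect_gt(max(spread), 0) # perturbation propagates to the edges
  }
})

test_that("degenerate all-zero measurements yield an empty-graph warning", {
  co <- tiny_cohort(1, design = tiny_design(n_subjects = 1, n_sessions = 1))
  m <- co$measurements[[1]][[1]][[1]]
  m$Y[] <- 0
  expect_warning(z <- reconstruct_connectome(m, "det"), "empty graph")
  expect_true(all(z$weights == 0))
})

test_that("subject-level deviation dominates subsample-level deviation", {
  # sigma_subject large vs sigma_subsample small: the across-subject %Dev
  # must exceed the across-subsample %Dev on a fixed seed.
  set <- tiny_set(7)
  subj <- group_stability(set, "subject")
  subs <- group_stability(set, "subsample")
  expect_gt(mean(subj$pairs$pdev), mean(subs$pairs$pdev))
})

test_that("increasing session variance increases across-session deviation", {
  d <- study_design(4, 2, 1, 24, 3, 0, pipelines = "det", modes = "dense")
  med <- vapply(c(0.05, 0.3, 0.9), function(sig) {
    co <- generate_cohort(d, n_nodes = 8, sigma_session = sig, seed = 31)
    set <- reconstruct_cohort(co, n_sims = 0, base_seed = 5)
    stats::median(group_stability(set, "session")$pairs$pdev)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("execution grid bookkeeping matches the index", {
  set <- tiny_set(7)
  d <- tiny_design()
  expect_equal(nrow(set$index), count_executions(d))
  expect_equal(sum(set$index$sim == 0),
               n_samples(d) * length(d$pipelines) * length(d$modes))
})
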