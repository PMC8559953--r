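test_that("percent deviation matches hand-computed anchors", {
  A <- matrix(c(0, 3, 3, 0), 2)
  B <- matrix(c(0, 4, 4, 0), 2)
  expect_equal(percent_deviation(A, A), 0)
  expect_equal(percent_deviation(A, matrix(0, 2, 2)), 1)
  expect_equal(percent_deviation(A, B), 1 / 3) # sqrt(2)/sqrt(18)
  expect_error(percent_deviation(matrix(0, 2, 2), A), "all-zero reference")
  expect_error(percent_deviation(A, matrix(0, 3, 3)), "shapes differ")
})

test_that("percent deviation is scale invariant and triangle consistent", {
  for (s in 1:20) {
    A <- random_connectome(6, seed = s)
    B <- random_connectome(6, seed = s + 100)
    C <- random_connectome(6, seed = s + 200)
    expect_equal(percent_deviation(2.7 * A, 2.7 * B), percent_deviation(A, B))
    expect_equal(percent_deviation(-3 * A, -3 * B), percent_deviation(A, B))
    lhs <- percent_deviation(A, B)
    rhs <- percent_deviation(A, C) +
      sqrt(sum((C - B)^2)) / sqrt(sum(A^2))
    expect_lte(lhs, rhs + 1e-12)
  }
})

test_that("significant digits: cap, closed forms, and degenerate cases", {
  expect_equal(significant_digits(rep(1.234, 5)), 15.7) # constant hits cap
  expect_equal(significant_digits(c(1 - 1e-3, 1, 1 + 1e-3)), 3,
               tolerance = 1e-6) # mu = 1, sd = 1e-3 (n-1 denominator)
  expect_equal(significant_digits(c(0.9, 1.0, 1.1)), 1) # sd = 0.1 (n-1)
  expect_equal(significant_digits(c(-1, 1)), 0)         # mu = 0, sd > 0
  expect_error(significant_digits(1.5), "insufficient")
  # matrix form: one value per column
  m <- rbind(c(1, 1, 5), c(1, 1.2, -5))
  d <- significant_digits(m)
  expect_equal(d[1], 15.7)
  expect_equal(d[3], 0)
  expect_true(d[2] > 0 && d[2] < 15.7)
})

test_that("significant digits decrease in the noise-to-signal ratio", {
  mu <- 2.5
  digits <- vapply(c(1e-12, 1e-8, 1e-4, 1e-2), function(sig) {
    x <- mu + sig * c(-1, 0, 1) # sd = sig exactly
    significant_digits(x)
  }, numeric(1))
  expect_true(all(diff(digits) < 0))
  # increasing |mu| at fixed spread increases digits
  expect_gt(significant_digits(c(99, 100, 101)),
            significant_digits(c(0.9, 1.0, 1.1)))
})

test_that("pearson correlation on upper triangles behaves", {
  A <- random_connectome(6, seed = 3)
  expect_equal(pearson_correlation(A, A), 1)
  expect_equal(pearson_correlation(A, 3 * A + 2), 1)
  anti <- matrix(0, 3, 3)
  anti[upper.tri(anti)] <- c(1, 2, 3)
  anti2 <- matrix(0, 3, 3)
  anti2[upper.tri(anti2)] <- c(3, 2, 1)
  expect_equal(pearson_correlation(anti + t(anti), anti2 + t(anti2)), -1)
  expect_warning(r <- pearson_correlation(matrix(1, 4, 4), A),
                 "zero-variance")
  expect_true(is.na(r))
})

test_that("group_stability enumerates pairs per comparison class", {
  set <- tiny_set(7) # 3 subjects x 2 sessions x 2 subsamples, 2 sims, det/dense
  mca <- group_stability(set, "mca")
  # one %Dev pair per (sample, sim): 12 samples x 2 sims
  expect_equal(nrow(mca$pairs), 24)
  expect_true(all(mca$pairs$pdev >= 0))
  expect_true(all(mca$pairs$pdev < 1e-8)) # ulp-scale noise only

  subs <- group_stability(set, "subsample")
  expect_equal(nrow(subs$pairs), 6) # one pair per subject x session
  sess <- group_stability(set, "session")
  expect_equal(nrow(sess$pairs), 3 * 4) # 2x2 cross-session ref pairs/subject
  subj <- group_stability(set, "subject")
  # refs: 12 per stratum; cross-subject pairs = C(12,2) - 3*C(4,2)
  expect_equal(nrow(subj$pairs), 66 - 18)
  expect_true(all(subj$digits$digits >= 0 & subj$digits$digits <= 15.7))
})

test_that("an identical duplicated cohort is perfectly stable", {
  W <- random_connectome(8, seed = 2)
  mk <- function(subject, session, subsample, sim) {
    list(weights = W, key = list(subject = subject, session = session,
                                 subsample = subsample, pipeline = "det",
                                 mode = "dense", sim = sim))
  }
  conns <- list(mk(1, 1, 1, 0), mk(1, 1, 1, 1), mk(1, 1, 1, 2),
                mk(1, 1, 2, 0), mk(1, 2, 1, 0), mk(2, 1, 1, 0))
  idx <- do.call(rbind, lapply(conns, function(cn) as.data.frame(cn$key)))
  set <- structure(list(connectomes = conns, index = idx),
                   class = "cs_connectome_set")
  for (cl in c("mca", "subsample", "session", "subject")) {
    r <- group_stability(set, cl)
    expect_true(all(r$pairs$pdev == 0))
    expect_true(all(r$digits$digits == 15.7))
  }
  # reference-vs-reference per-edge digits are all at the cap
  expect_equal(unname(significant_digits(rbind(upper_triangle(W),
                                               upper_triangle(W)))),
               rep(15.7, 28))
})

test_that("median deviation orders mca < subsample < session < subject", {
  set <- tiny_set(7)
  med <- vapply(c("mca", "subsample", "session", "subject"), function(cl) {
    stats::median(group_stability(set, cl)$pairs$pdev)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  # and the noise floor sits far below the acquisition-level differences
  expect_lt(med["mca"] * 1e3, med["subsample"])
})

test_that("empty comparison classes raise errors", {
  set <- tiny_set(7)
  solo <- subset_connectomes(set, set$index$subject == 1 &
                               set$index$session == 1)
  expect_error(group_stability(solo, "session"), "empty class")
  refs <- subset_connectomes(set, set$index$sim == 0)
  expect_error(group_stability(refs, "mca"), "empty class")
})

test_that("stability reports serialize to CSV and JSON", {
  set <- tiny_set(7)
  rep_ <- group_stability(set, "mca")
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  smry <- write_stability(rep_, csv = csv, json = js)
  expect_equal(nrow(utils::read.csv(csv)), nrow(rep_$pairs))
  got <- jsonlite::read_json(js)
  expect_equal(got$n_pairs, smry$n_pairs)
  expect_equal(got$class, "mca")
})
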