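#' Select the PCA component count from cross-validation training sets
#'
#' Fits a PCA on the training rows of each fold and returns the smallest
#' component count whose cumulative explained-variance fraction, averaged
#' across the folds' training sets, exceeds `threshold`. If no count
#' reaches the threshold (rank-deficient degenerate input), the full rank
#' is returned with a warning.
#'
#' @param x observations x features matrix.
#' @param folds list of test-index vectors (as produced by
#'   [stratified_folds()]); training rows are the complement.
#' @param threshold explained-variance threshold (default 0.9).
#' @return integer component count.
#' @export
select_components <- function(x, folds, threshold = 0.9) {
  x <- as.matrix(x)
  cum <- lapply(folds, function(te) {
    tr <- setdiff(seq_len(nrow(x)), te)
    if (length(tr) < 2) stop("need >= 2 training samples per fold")
    pc <- stats::prcomp(x[tr, , drop = FALSE], center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    cumsum(v) / sum(v)
  })
  k <- min(lengths(cum))
  mean_cum <- rowMeans(vapply(cum, function(v) v[seq_len(k)], numeric(k)))
  hit <- which(mean_cum > threshold)
  if (!length(hit)) {
    warning("explained-variance threshold unreachable; using full rank")
    return(k)
  }
  hit[1]
}

#' Stratified k-fold assignment
#'
#' @param labels binary labels.
#' @param k number of folds (`k = length(labels)` gives leave-one-out).
#' @param seed fold-assignment seed.
#' @return list of `k` test-index vectors covering all observations.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  stopifnot(k >= 2, k <= n)
  if (k == n) return(as.list(seq_len(n))) # leave-one-out
  with_seed(derive_seed(seed, 23L), {
    fold <- integer(n)
    for (cls in unique(labels)) {
      ii <- sample(which(labels == cls))
      fold[ii] <- rep_len(seq_len(k), length(ii))
    }
    split(seq_len(n), fold)
  })
}

# Ridge-penalized logistic regression via iteratively reweighted least
# squares; the intercept is unpenalized. Fixed penalty keeps the fit
# deterministic and well-defined even with a single predictor.
ridge_logistic <- function(X, y, lambda = 1.0, max_iter = 100L, tol = 1e-10) {
  X1 <- cbind(1, as.matrix(X))
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1, X1 * w) + pen
    score <- crossprod(X1, y - mu) - pen %*% beta
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

predict_ridge <- function(beta, X) {
  stats::plogis(drop(cbind(1, as.matrix(X)) %*% beta))
}

binary_f1 <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Cross-validated PCA + logistic classification of a cohort
#'
#' Stratified k-fold cross-validation of the brain-phenotype model:
#' dimensionality reduction by PCA and a ridge-penalized logistic
#' classifier. The component count is selected from the folds' training
#' sets only (see [select_components()]); within each fold, the PCA basis
#' and the classifier are fit on the training rows alone, and accuracy and
#' F1 (binary positive class) are pooled over the held-out predictions.
#'
#' @param x observations x features matrix (one connectome vector per
#'   subject).
#' @param labels binary labels (0/1), both classes present.
#' @param k folds: 2, 5, 10, or `nrow(x)` for leave-one-out.
#' @param seed fold-assignment seed.
#' @param lambda ridge penalty of the classifier.
#' @param threshold explained-variance threshold for component selection.
#' @param n_components optional fixed component count, bypassing
#'   [select_components()] (used e.g. to assert leak-free per-fold fits).
#' @return an object of class `cs_modelrun`: `k`, `n_components`,
#'   `explained_variance` (mean training-set fraction at the selected
#'   count), pooled `accuracy` and `f1`, `per_fold` diagnostics, and the
#'   held-out `predictions`.
#' @export
classify_cohort <- function(x, labels, k = 5L, seed = 1L, lambda = 1.0,
                            threshold = 0.9, n_components = NULL) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(x))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  folds <- stratified_folds(labels, k, seed)
  bad <- vapply(folds, function(te) {
    length(unique(labels[-te])) < 2
  }, logical(1))
  if (any(bad)) stop("stratification error: single-class training fold")
  ncomp <- if (is.null(n_components)) select_components(x, folds, threshold)
           else as.integer(n_components)

  pred <- integer(length(labels))
  prob <- numeric(length(labels))
  per_fold <- list()
  expl <- numeric(length(folds))
  for (fi in seq_along(folds)) {
    te <- folds[[fi]]
    tr <- setdiff(seq_len(nrow(x)), te)
    pc <- stats::prcomp(x[tr, , drop = FALSE], center = TRUE, scale. = FALSE)
    nc <- min(ncomp, ncol(pc$rotation))
    v <- pc$sdev^2
    expl[fi] <- sum(v[seq_len(nc)]) / sum(v)
    ztr <- pc$x[, seq_len(nc), drop = FALSE]
    zte <- scale(x[te, , drop = FALSE], center = pc$center, scale = FALSE) %*%
      pc$rotation[, seq_len(nc), drop = FALSE]
    # standardize scores on the training scale so the ridge penalty is
    # commensurate regardless of the connectomes' weight normalization
    sds <- pmax(apply(ztr, 2, stats::sd), 1e-12)
    ztr <- sweep(ztr, 2, sds, `/`)
    zte <- sweep(zte, 2, sds, `/`)
    beta <- ridge_logistic(ztr, labels[tr], lambda = lambda)
    prob[te] <- predict_ridge(beta, zte)
    pred[te] <- as.integer(prob[te] > 0.5)
    per_fold[[fi]] <- list(test = te, beta = beta,
                           accuracy = mean(pred[te] == labels[te]))
  }
  structure(
    list(k = as.integer(k), n_components = as.integer(ncomp),
         explained_variance = mean(expl),
         accuracy = mean(pred == labels),
         f1 = binary_f1(labels, pred),
         per_fold = per_fold, predictions = pred, probabilities = prob,
         seed = as.integer(seed)),
    class = "cs_modelrun"
  )
}

#' @export
print.cs_modelrun <- function(x, ...) {
  cat(sprintf(
    "<cs_modelrun> k = %d, %d components (%.1f%% variance): accuracy = %.3f, F1 = %.3f\n",
    x$k, x$n_components, 100 * x$explained_variance, x$accuracy, x$f1))
  invisible(x)
}

#' Classification variability under perturbation resampling
#'
#' Draws, for each of `n_repeats` resamplings, one perturbed connectome per
#' subject uniformly at random (seeded), refits the PCA + logistic model,
#' and records its metrics; the reference-connectome run is reported
#' alongside with the min/max/mean envelope across repeats.
#'
#' @param x_by_subject list over subjects; each element a matrix of
#'   vectorized perturbed connectomes (one row per simulation, >= 1).
#' @param x_reference matrix of reference connectome vectors (one row per
#'   subject).
#' @param labels binary labels per subject.
#' @param k,lambda,threshold model settings (see [classify_cohort()]).
#' @param n_repeats number of dataset resamplings (default 20).
#' @param seed master seed. Each repeat derives its own data-sampling
#'   stream; the fold assignment is held fixed across repeats and the
#'   reference run, so performance spread is attributable to the
#'   perturbation resampling alone.
#' @return list with `runs` (data frame of per-repeat metrics),
#'   `reference` (the reference `cs_modelrun`), and `summary`
#'   (min/max/mean accuracy, F1, explained variance).
#' @export
resampled_performance <- function(x_by_subject, x_reference, labels,
                                  k = 5L, n_repeats = 20L, seed = 1L,
                                  lambda = 1.0, threshold = 0.9) {
  stopifnot(n_repeats >= 1, is.list(x_by_subject))
  n <- length(x_by_subject)
  stopifnot(nrow(x_reference) == n, length(labels) == n)
  ref <- classify_cohort(x_reference, labels, k = k,
                         seed = derive_seed(seed, 0L), lambda = lambda,
                         threshold = threshold)
  rows <- lapply(seq_len(n_repeats), function(r) {
    xi <- with_seed(derive_seed(seed, r, 31L), {
      t(vapply(x_by_subject, function(m) {
        m <- as.matrix(m)
        m[sample.int(nrow(m), 1L), ]
      }, numeric(ncol(x_reference))))
    })
    run <- classify_cohort(xi, labels, k = k, seed = derive_seed(seed, 0L),
                           lambda = lambda, threshold = threshold)
    data.frame(repeat_id = r, accuracy = run$accuracy, f1 = run$f1,
               n_components = run$n_components,
               explained_variance = run$explained_variance)
  })
  runs <- do.call(rbind, rows)
  list(runs = runs, reference = ref,
       summary = list(
         accuracy = c(min = min(runs$accuracy), mean = mean(runs$accuracy),
                      max = max(runs$accuracy)),
         f1 = c(min = min(runs$f1), mean = mean(runs$f1), max = max(runs$f1)),
         explained_variance = c(min = min(runs$explained_variance),
                                mean = mean(runs$explained_variance),
                                max = max(runs$explained_variance)),
         reference_accuracy = ref$accuracy, reference_f1 = ref$f1))
}
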