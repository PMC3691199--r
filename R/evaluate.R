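#' Pool patch-level feature activations into one per-sequence vector
#'
#' Each patch's hidden activations are rescaled by that patch's
#' pre-standardization standard deviation (restoring amplitude information
#' the per-patch standardization removed), then the per-feature maximum over
#' the sequence's patches is kept. The mean, maximum, minimum, standard
#' deviation and range of the patch sds are appended, giving
#' `n_hidden + 5` features (105 at the default 100 hidden units).
#'
#' @param activations `n_hidden` x n_patches matrix of activations for one
#'   sequence's patches (a vector is treated as a single feature row).
#' @param patch_sd numeric vector of per-patch standard deviations, length
#'   n_patches.
#' @return numeric feature vector of length `nrow(activations) + 5`.
#' @export
pool_sequence_features <- function(activations, patch_sd) {
  A <- as.matrix(activations)
  check_that(ncol(A) >= 1, "sequence has zero patches")
  check_that(ncol(A) == length(patch_sd),
             "activations columns must match patch_sd length")
  resc <- sweep(A, 2, patch_sd, "*")
  pooled <- apply(resc, 1, max)
  sd_sd <- if (length(patch_sd) > 1) stats::sd(patch_sd) else 0
  c(pooled, mean(patch_sd), max(patch_sd), min(patch_sd), sd_sd,
    diff(range(patch_sd)))
}

#' Expert-engineered comparator features
#'
#' The 11 hand-designed features capturing the clinically salient differences
#' between gout-like and leukemia-like uric acid sequences: observation count
#' n; time span T (days); observation density n/T; steepest positive and
#' steepest negative slope between neighboring observations (value units per
#' day; 0 if no slope of that sign exists); standard deviation of all
#' neighbor slopes; minimum, maximum, mean and standard deviation of the
#' measured values; and the fraction of (globally standardized) values
#' exceeding `threshold`.
#'
#' @param sequence an [obs_sequence()]; in the pipeline the values have
#'   already been globally standardized, so the threshold feature is on the
#'   standardized scale.
#' @param threshold cutoff for the final fraction feature (default 1.5).
#' @return named numeric vector of length 11.
#' @export
engineered_features <- function(sequence, threshold = 1.5) {
  t <- sequence$times
  v <- sequence$values
  n <- length(v)
  check_that(n >= 2, "need at least two observations")
  span <- t[n] - t[1]
  check_that(span > 0, "all observations co-timed: density n/T undefined")
  slopes <- diff(v) / diff(t)
  pos <- slopes[slopes > 0]
  neg <- slopes[slopes < 0]
  c(n_obs = n,
    span_days = span,
    density = n / span,
    steepest_pos_slope = if (length(pos)) max(pos) else 0,
    steepest_neg_slope = if (length(neg)) min(neg) else 0,
    slope_sd = if (length(slopes) > 1) stats::sd(slopes) else 0,
    value_min = min(v),
    value_max = max(v),
    value_mean = mean(v),
    value_sd = stats::sd(v),
    frac_above = mean(v > threshold))
}

#' Baseline comparator feature: the sequence mean
#'
#' @param sequence an [obs_sequence()] (standardized values in the pipeline).
#' @return numeric vector of length 1.
#' @export
baseline_feature <- function(sequence) {
  c(value_mean = mean(sequence$values))
}

#' Train an elastic-net logistic classifier
#'
#' Penalized logistic regression with the elastic-net penalty at a mixing
#' weight heavily toward the L1 (feature-selecting) end, the penalty
#' strength chosen along the regularization path by k-fold cross-validated
#' deviance. Features are column-standardized internally from the training
#' data only. Deterministic under `seed` (which fixes the CV fold
#' assignment).
#'
#' @param x numeric feature matrix, rows = sequences. A single-column matrix
#'   is padded internally with one all-zero column (which receives a zero
#'   coefficient) to satisfy the fitting routine.
#' @param y labels; coerced to factor, must have exactly 2 levels with the
#'   second level treated as the positive class.
#' @param alpha elastic-net mixing weight (default 0.95).
#' @param nfolds cross-validation folds (default 5).
#' @param seed integer seed.
#' @return object of class `phenotype_classifier`.
#' @export
train_classifier <- function(x, y, alpha = 0.95, nfolds = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  check_that(nlevels(y) == 2, "both classes must be present")
  check_that(nrow(x) == length(y), "x rows must match labels")
  padded <- ncol(x) == 1L
  if (padded) x <- cbind(x, pad0 = 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                          nfolds = nfolds, type.measure = "deviance",
                          standardize = TRUE)
  structure(list(cv = cv, lambda = cv$lambda.min, levels = levels(y),
                 alpha = alpha, nfolds = nfolds, padded = padded),
            class = "phenotype_classifier")
}

#' Score sequences with a trained classifier
#'
#' @param object a `phenotype_classifier`.
#' @param newx feature matrix with the training column layout.
#' @param ... unused.
#' @return numeric vector of predicted probabilities of the positive
#'   (second-level) class.
#' @export
predict.phenotype_classifier <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (object$padded) newx <- cbind(newx, pad0 = 0)
  drop(stats::predict(object$cv, newx = newx, s = object$lambda,
                      type = "response"))
}

#' Empirical (nonparametric) AUC
#'
#' The Mann-Whitney statistic: the fraction of (positive, negative) pairs in
#' which the positive scores higher, ties counted one half. Invariant under
#' any strictly increasing transform of the scores.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param labels two-level labels; second factor level is positive.
#' @return AUC in [0, 1].
#' @export
auc_empirical <- function(scores, labels) {
  labels <- factor(labels)
  check_that(nlevels(labels) == 2, "both classes must be present")
  check_that(length(scores) == length(labels), "scores/labels mismatch")
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# BCa interval from bootstrap statistics, a bias-correction z0 and an
# acceleration a; z0 = a = 0 reduces it to the percentile interval.
bca_interval <- function(stats_boot, z0, accel, conf = 0.95) {
  zl <- stats::qnorm((1 - conf) / 2)
  zu <- -zl
  p_lo <- stats::pnorm(z0 + (z0 + zl) / (1 - accel * (z0 + zl)))
  p_hi <- stats::pnorm(z0 + (z0 + zu) / (1 - accel * (z0 + zu)))
  unname(stats::quantile(stats_boot, c(p_lo, p_hi), type = 6))
}

#' BCa bootstrap confidence interval for the empirical AUC
#'
#' Resamples (score, label) pairs with replacement, recomputes the AUC, and
#' forms the bias-corrected and accelerated interval: the bias correction z0
#' comes from the fraction of bootstrap statistics below the point estimate
#' and the acceleration from the jackknife skewness of the statistic.
#' Resamples that lose one class entirely are redrawn (up to a retry cap)
#' and counted in the `"n_redrawn"` attribute.
#'
#' @inheritParams auc_empirical
#' @param n_boot bootstrap iterations (default 30).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(ci_low, ci_high)` with attribute `auc` (the point
#'   estimate).
#' @export
auc_ci_bootstrap <- function(scores, labels, n_boot = 30L, seed = 1L,
                             conf = 0.95) {
  labels <- factor(labels)
  check_that(nlevels(labels) == 2, "both classes must be present")
  check_that(is_count(n_boot) && n_boot >= 2, "n_boot must be >= 2")
  n <- length(scores)
  theta <- auc_empirical(scores, labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  stats_boot <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      if (nlevels(droplevels(labels[idx])) == 2) break
      n_redrawn <- n_redrawn + 1L
      if (try == 100) stop("could not draw a two-class bootstrap resample")
    }
    stats_boot[b] <- auc_empirical(scores[idx], labels[idx])
  }
  prop <- mean(stats_boot < theta) + 0.5 * mean(stats_boot == theta)
  z0 <- stats::qnorm(min(max(prop, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot)))
  # jackknife acceleration
  jack <- vapply(seq_len(n), function(i) {
    li <- droplevels(labels[-i])
    if (nlevels(li) < 2) theta else auc_empirical(scores[-i], labels[-i])
  }, numeric(1))
  d <- mean(jack) - jack
  denom <- 6 * sum(d^2)^1.5
  accel <- if (denom > 0) sum(d^3) / denom else 0
  ci <- bca_interval(stats_boot, z0, accel, conf)
  attr(ci, "auc") <- theta
  attr(ci, "n_redrawn") <- n_redrawn
  ci
}

#' 2-D embedding of a feature space
#'
#' t-SNE embedding (via the Rtsne package) of per-sequence feature vectors,
#' used to look for subpopulation structure. Perplexity sets the neighbor
#' length scale: 20 is the default for learned feature spaces, 5 suits the
#' low-dimensional engineered space.
#'
#' @param x numeric feature matrix, rows = sequences; needs more than
#'   `3 * perplexity` rows.
#' @param perplexity t-SNE perplexity (default 20).
#' @param seed integer seed.
#' @return n x 2 matrix of coordinates.
#' @export
embed_2d <- function(x, perplexity = 20, seed = 1L) {
  x <- as.matrix(x)
  check_that(nrow(x) > 3 * perplexity,
             sprintf("need more than %d instances for perplexity %g",
                     ceiling(3 * perplexity), perplexity))
  if (!requireNamespace("Rtsne", quietly = TRUE))
    stop("embed_2d needs the Rtsne package", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                      check_duplicates = FALSE, pca = ncol(x) > 50,
                      verbose = FALSE)
  fit$Y
}
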