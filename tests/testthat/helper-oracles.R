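# Brute-force oracles, deliberately independent of the package's Cholesky
# code paths (these use solve() and determinant() on the full joint system).

mvn_logdensity_oracle <- function(times, values, hp, kernel = "rq") {
  kf <- if (kernel == "rq") cov_rational_quadratic else cov_squared_exponential
  n <- length(values)
  K <- outer(times, times, function(a, b) kf(a, b, hp)) + diag(hp$noise_sd^2, n)
  -0.5 * drop(values %*% solve(K, values)) -
    0.5 * determinant(K, logarithm = TRUE)$modulus[1] -
    n / 2 * log(2 * pi)
}

# Gaussian conditioning of the joint (obs, query) system; predictive of a
# new measurement, so the query variance includes the noise term.
gp_conditional_oracle <- function(times, values, query, hp, kernel = "rq") {
  kf <- if (kernel == "rq") cov_rational_quadratic else cov_squared_exponential
  n <- length(times)
  Ky <- outer(times, times, function(a, b) kf(a, b, hp)) + diag(hp$noise_sd^2, n)
  ks <- outer(query, times, function(a, b) kf(a, b, hp))
  mu <- drop(ks %*% solve(Ky, values))
  var <- kf(query, query, hp) + hp$noise_sd^2 -
    rowSums(ks * t(solve(Ky, t(ks))))
  list(mu = mu, sigma = sqrt(var))
}

# random irregular standardized sequence on [0, span] days
rand_gp_sequence <- function(n, span = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- sort(c(0, runif(n - 1, 0, span)))
  list(times = times, values = rnorm(n), record_id = "rnd")
}

# central finite-difference gradient of total_cost at a packed parameter
fd_gradient <- function(X, S, config, theta, eps = 1e-6) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (total_cost(X, S, phenolearn:::unpack_params(tp, config))$cost -
       total_cost(X, S, phenolearn:::unpack_params(tm, config))$cost) / (2 * eps)
  }, numeric(1))
}

# small standardized patch batch for autoencoder tests
toy_patch_batch <- function(n_input = 8, m = 6, seed = 11) {
  set.seed(seed)
  X <- matrix(rnorm(n_input * m), n_input, m)
  X <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), "/")
  S <- matrix(runif(n_input * m, 0.5, 2), n_input, m)
  list(X = X, S = S)
}

# quick small density for patch-level tests
toy_density <- function(span_days = 365, seed = 4) {
  set.seed(seed)
  grid <- 0:span_days
  structure(list(record_id = "toy", label = "unlabeled", grid_times = grid,
                 mu = sin(grid / 20) + rnorm(length(grid), 0, 0.05),
                 sigma = runif(length(grid), 0.2, 0.6)),
            class = "longitudinal_density")
}

# exhaustive pair-counting AUC (ties = 1/2), the comparison standard for
# the rank-based implementation
auc_pairs_oracle <- function(scores, labels) {
  labels <- factor(labels)
  pos <- scores[labels == levels(labels)[2]]
  neg <- scores[labels == levels(labels)[1]]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
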