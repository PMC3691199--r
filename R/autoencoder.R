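#' Extract standardized 30-day patches from a longitudinal density
#'
#' Randomly extracts fixed-length windows of contiguous daily values from a
#' density's posterior mean, with the corresponding posterior standard
#' deviations. Each patch is standardized to zero mean / unit standard
#' deviation of its mu values (sigma is scaled by the same per-patch sd), and
#' thereafter treated as an independent training instance, ignoring its
#' sequence of origin; the per-patch statistics are retained for later
#' rescaling. Extraction count is `max(1, round(rate * span/365))` where span
#' is the days covered by the density grid.
#'
#' Patches whose pre-standardization sd is below `1e-8` (flat density) are
#' dropped; the dropped count is recorded in the `"n_dropped"` attribute.
#'
#' @param density a [posterior_density()] result.
#' @param rate patches per 365 days of span (default 50).
#' @param window patch length in days (default 30).
#' @param seed integer seed for the uniform window starts.
#' @return object of class `patch_set`: matrices `mu` and `sigma`
#'   (window x n_patches), vectors `record_id`, `start_day`, `patch_mean`,
#'   `patch_sd`. Empty (0 patches, with a warning) if the grid is shorter
#'   than the window.
#' @export
extract_patches <- function(density, rate = 50, window = 30, seed = 1L) {
  ng <- length(density$grid_times)
  if (ng < window) {
    warning(sprintf("density %s grid (%d) shorter than window (%d); skipped",
                    density$record_id, ng, window))
    return(empty_patch_set(window))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  span <- diff(range(density$grid_times))
  count <- max(1L, round(rate * span / 365))
  starts <- sample.int(ng - window + 1L, count, replace = TRUE)
  mu <- vapply(starts, function(s) density$mu[s:(s + window - 1L)],
               numeric(window))
  sg <- vapply(starts, function(s) density$sigma[s:(s + window - 1L)],
               numeric(window))
  mu <- matrix(mu, nrow = window)
  sg <- matrix(sg, nrow = window)
  pm <- colMeans(mu)
  psd <- apply(mu, 2, stats::sd)
  keep <- psd >= 1e-8
  ps <- structure(
    list(mu = sweep(sweep(mu[, keep, drop = FALSE], 2, pm[keep]), 2,
                    psd[keep], "/"),
         sigma = sweep(sg[, keep, drop = FALSE], 2, psd[keep], "/"),
         record_id = rep(density$record_id, sum(keep)),
         start_day = starts[keep],
         patch_mean = pm[keep], patch_sd = psd[keep],
         window = window),
    class = "patch_set")
  attr(ps, "n_dropped") <- sum(!keep)
  ps
}

empty_patch_set <- function(window) {
  structure(list(mu = matrix(numeric(0), window, 0),
                 sigma = matrix(numeric(0), window, 0),
                 record_id = character(0), start_day = integer(0),
                 patch_mean = numeric(0), patch_sd = numeric(0),
                 window = window),
            class = "patch_set")
}

#' Concatenate patch sets
#'
#' @param ... `patch_set` objects (or a single list of them).
#' @return one combined `patch_set`.
#' @export
bind_patches <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "patch_set")) sets <- sets[[1]]
  structure(list(mu = do.call(cbind, lapply(sets, `[[`, "mu")),
                 sigma = do.call(cbind, lapply(sets, `[[`, "sigma")),
                 record_id = unlist(lapply(sets, `[[`, "record_id")),
                 start_day = unlist(lapply(sets, `[[`, "start_day")),
                 patch_mean = unlist(lapply(sets, `[[`, "patch_mean")),
                 patch_sd = unlist(lapply(sets, `[[`, "patch_sd")),
                 window = sets[[1]]$window),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d days from %d sequences\n",
              ncol(x$mu), x$window, length(unique(x$record_id))))
  invisible(x)
}

#' Sparse-autoencoder layer configuration
#'
#' One layer of the stacked sparse autoencoder: a sigmoid encoder
#' h = sigmoid(W x + b) and a linear decoder (inputs are continuous in both
#' layers), trained with a reconstruction loss plus an L2 weight penalty
#' (weight `lambda`) and a KL sparsity penalty (weight `beta`) driving each
#' hidden unit's batch-average activation toward the target `rho`. Layer 1
#' reconstructs density-mean patches under the uncertainty-normalized loss;
#' layer 2 reconstructs layer-1 activations under plain squared error.
#'
#' @param n_input input dimension (30 for density patches).
#' @param n_hidden hidden units (default 100).
#' @param rho sparsity target in (0,1) (default 0.05).
#' @param beta sparsity penalty weight (default 3).
#' @param lambda L2 regularization weight (default 3e-4).
#' @param loss `"normalized_squared_error"` (sigma-weighted; layer 1) or
#'   `"squared_error"` (layer 2).
#' @param sigma_power exponent on sigma in the normalized loss denominator;
#'   2 (default) makes the loss the kernel of a Gaussian log-likelihood.
#' @param tied if TRUE the decoder weights are the transpose of the encoder
#'   weights rather than learned separately.
#' @return list of class `layer_config`.
#' @export
layer_config <- function(n_input, n_hidden = 100L, rho = 0.05, beta = 3,
                         lambda = 3e-4,
                         loss = c("normalized_squared_error", "squared_error"),
                         sigma_power = 2, tied = FALSE) {
  loss <- match.arg(loss)
  check_that(is_count(n_input) && n_input > 0, "n_input must be a positive count")
  check_that(is_count(n_hidden) && n_hidden > 0, "n_hidden must be a positive count")
  check_that(is.numeric(rho) && rho > 0 && rho < 1, "rho must lie in (0,1)")
  check_that(is.numeric(beta) && beta >= 0, "beta must be >= 0")
  check_that(is.numeric(lambda) && lambda >= 0, "lambda must be >= 0")
  structure(list(n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
                 rho = rho, beta = beta, lambda = lambda, loss = loss,
                 sigma_power = sigma_power, tied = isTRUE(tied)),
            class = "layer_config")
}

# Seeded symmetric-uniform initialization on +/- sqrt(6/(fan_in+fan_out+1));
# biases zero.
init_layer <- function(config, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  r <- sqrt(6 / (config$n_input + config$n_hidden + 1))
  W_enc <- matrix(stats::runif(config$n_hidden * config$n_input, -r, r),
                  config$n_hidden, config$n_input)
  W_dec <- if (config$tied) t(W_enc)
           else matrix(stats::runif(config$n_input * config$n_hidden, -r, r),
                       config$n_input, config$n_hidden)
  structure(list(W_enc = W_enc, b_enc = numeric(config$n_hidden),
                 W_dec = W_dec, b_dec = numeric(config$n_input),
                 config = config),
            class = "autoencoder_layer")
}

#' @export
print.autoencoder_layer <- function(x, ...) {
  cat(sprintf("<autoencoder_layer> %d -> %d (%s%s)\n", x$config$n_input,
              x$config$n_hidden, x$config$loss,
              if (x$config$tied) ", tied" else ""))
  invisible(x)
}

#' Encode inputs into hidden activations
#'
#' h = sigmoid(W_enc x + b_enc); every activation lies in (0, 1). The rows of
#' `W_enc` are the learned features; `h[k]` measures how strongly feature k
#' is present in the input.
#'
#' @param x numeric vector of length `n_input`, or a matrix with one column
#'   per instance.
#' @param layer an `autoencoder_layer`.
#' @return activation vector (or `n_hidden` x m matrix).
#' @export
encode <- function(x, layer) {
  x <- as.matrix(x)
  check_that(nrow(x) == layer$config$n_input,
             sprintf("input dimension %d != layer n_input %d", nrow(x),
                     layer$config$n_input))
  h <- sigmoid(layer$W_enc %*% x + layer$b_enc)
  if (ncol(h) == 1L) drop(h) else h
}

#' Decode hidden activations into a reconstruction
#'
#' Linear decoder: x_hat = W_dec h + b_dec (the inputs are continuous).
#'
#' @param h activation vector of length `n_hidden`, or matrix (columns =
#'   instances).
#' @param layer an `autoencoder_layer`.
#' @return reconstruction vector (or matrix).
#' @export
decode <- function(h, layer) {
  h <- as.matrix(h)
  check_that(nrow(h) == layer$config$n_hidden,
             sprintf("hidden dimension %d != layer n_hidden %d", nrow(h),
                     layer$config$n_hidden))
  out <- layer$W_dec %*% h + layer$b_dec
  if (ncol(out) == 1L) drop(out) else out
}

#' Uncertainty-normalized squared reconstruction error
#'
#' (1/2) * sum((x_mu - x_hat)^2 / x_sigma^2): reconstruction errors are
#' discounted where the density's posterior uncertainty is high, so the
#' autoencoder spends its capacity where the GP is confident.
#'
#' @param x_mu,x_sigma,x_hat equal-length numeric vectors; `x_sigma > 0`.
#' @return non-negative scalar; zero iff the reconstruction is perfect.
#' @export
loss_normalized_squared_error <- function(x_mu, x_sigma, x_hat) {
  check_that(length(x_mu) == length(x_sigma) &&
               length(x_mu) == length(x_hat), "length mismatch")
  check_that(all(x_sigma > 0), "x_sigma must be strictly positive")
  0.5 * sum((x_mu - x_hat)^2 / x_sigma^2)
}

#' Bernoulli KL divergence used as the sparsity penalty
#'
#' KL(rho || rho_hat) = rho log(rho/rho_hat) + (1-rho) log((1-rho)/(1-rho_hat));
#' non-negative, zero iff rho_hat == rho.
#'
#' @param rho sparsity target in (0,1).
#' @param rho_hat observed average activation(s) in (0,1); vectorized.
#' @return divergence value(s).
#' @export
kl_sparsity <- function(rho, rho_hat) {
  check_that(all(rho > 0 & rho < 1) && all(rho_hat > 0 & rho_hat < 1),
             "rho and rho_hat must lie strictly in (0,1)")
  rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat))
}

# pack/unpack the trainable parameters into a flat vector for the optimizer
pack_params <- function(layer) {
  if (layer$config$tied) c(layer$W_enc, layer$b_enc, layer$b_dec)
  else c(layer$W_enc, layer$b_enc, layer$W_dec, layer$b_dec)
}

unpack_params <- function(theta, config) {
  nh <- config$n_hidden; ni <- config$n_input
  W_enc <- matrix(theta[seq_len(nh * ni)], nh, ni)
  off <- nh * ni
  b_enc <- theta[off + seq_len(nh)]; off <- off + nh
  if (config$tied) {
    W_dec <- t(W_enc)
  } else {
    W_dec <- matrix(theta[off + seq_len(ni * nh)], ni, nh)
    off <- off + ni * nh
  }
  b_dec <- theta[off + seq_len(ni)]
  structure(list(W_enc = W_enc, b_enc = b_enc, W_dec = W_dec, b_dec = b_dec,
                 config = config), class = "autoencoder_layer")
}

#' Overall sparse-autoencoder cost and gradient on a batch
#'
#' Mean reconstruction loss over the batch (sigma-normalized squared error
#' for a layer configured with `loss = "normalized_squared_error"`, plain
#' squared error otherwise) plus `lambda/2` times the summed squared encoder
#' and decoder weights plus `beta` times the summed [kl_sparsity()] between
#' the target `rho` and each hidden unit's batch-average activation. The
#' returned gradient is the exact analytic gradient of this cost with
#' respect to all weights and biases (packed encoder-bias-decoder-bias).
#'
#' @param X `n_input` x m matrix of inputs (standardized patch means, or
#'   lower-layer activations).
#' @param S `n_input` x m matrix of scaled patch sigmas (ignored for plain
#'   squared error; may be NULL then).
#' @param layer an `autoencoder_layer`.
#' @return list with `cost` (scalar) and `grad` (numeric vector matching
#'   `pack_params(layer)`).
#' @export
total_cost <- function(X, S, layer) {
  cfg <- layer$config
  m <- ncol(X)
  check_that(m >= 1, "empty batch")
  normalized <- cfg$loss == "normalized_squared_error"
  if (normalized) {
    check_that(!is.null(S) && all(dim(S) == dim(X)), "S must match X")
    iv <- 1 / S^cfg$sigma_power
  }
  Z <- layer$W_enc %*% X + layer$b_enc
  H <- sigmoid(Z)
  Xhat <- layer$W_dec %*% H + layer$b_dec
  R <- Xhat - X
  if (normalized) {
    cost_rec <- 0.5 * sum(R^2 * iv) / m
    delta <- (R * iv) / m
  } else {
    cost_rec <- 0.5 * sum(R^2) / m
    delta <- R / m
  }
  rho_hat <- pmin(pmax(rowMeans(H), 1e-12), 1 - 1e-12)
  cost <- cost_rec +
    cfg$lambda / 2 * (sum(layer$W_enc^2) + if (cfg$tied) 0 else sum(layer$W_dec^2)) +
    cfg$beta * sum(kl_sparsity(cfg$rho, rho_hat))
  gW_dec <- tcrossprod(delta, H)
  gb_dec <- rowSums(delta)
  sparse_grad <- cfg$beta * (-cfg$rho / rho_hat + (1 - cfg$rho) / (1 - rho_hat)) / m
  Dh <- (crossprod(layer$W_dec, delta) + sparse_grad) * H * (1 - H)
  gW_enc <- tcrossprod(Dh, X)
  if (cfg$tied) {
    gW_enc <- gW_enc + t(gW_dec) + cfg$lambda * layer$W_enc
    grad <- c(gW_enc, rowSums(Dh), gb_dec)
  } else {
    grad <- c(gW_enc + cfg$lambda * layer$W_enc, rowSums(Dh),
              gW_dec + cfg$lambda * layer$W_dec, gb_dec)
  }
  list(cost = cost, grad = grad)
}

#' Train one autoencoder layer
#'
#' Full-batch quasi-Newton (L-BFGS-B) minimization of [total_cost()] from a
#' seeded small-variance symmetric random initialization. Deterministic under
#' fixed inputs, config and seed. `maxit = 0` returns the initialized layer
#' unchanged.
#'
#' @param X input matrix (`n_input` x m), or a `patch_set` (its `mu`/`sigma`
#'   are used).
#' @param config a [layer_config()].
#' @param S sigma matrix matching X (taken from the `patch_set` if one is
#'   given).
#' @param maxit optimizer iteration cap (default 400).
#' @param seed weight-initialization seed.
#' @return trained `autoencoder_layer` with attributes `cost_initial`,
#'   `cost_final`, `convergence`.
#' @export
train_layer <- function(X, config, S = NULL, maxit = 400L, seed = 1L) {
  if (inherits(X, "patch_set")) {
    S <- X$sigma
    X <- X$mu
  }
  check_that(ncol(X) >= 1, "need at least one training instance")
  check_that(nrow(X) == config$n_input, "X rows must equal config n_input")
  layer <- init_layer(config, seed)
  theta0 <- pack_params(layer)
  fn <- function(th) {
    v <- total_cost(X, S, unpack_params(th, config))$cost
    if (!is.finite(v)) stop("optimizer diverged: non-finite cost", call. = FALSE)
    v
  }
  gr <- function(th) total_cost(X, S, unpack_params(th, config))$grad
  c0 <- fn(theta0)
  if (maxit == 0L) {
    attr(layer, "cost_initial") <- c0
    attr(layer, "cost_final") <- c0
    attr(layer, "convergence") <- 0L
    return(layer)
  }
  fit <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4))
  out <- if (fit$value <= c0) unpack_params(fit$par, config) else layer
  attr(out, "cost_initial") <- c0
  attr(out, "cost_final") <- min(fit$value, c0)
  attr(out, "convergence") <- fit$convergence
  out
}

#' Train a two-layer stacked sparse autoencoder
#'
#' Layers are trained individually from the bottom up: layer 1 on the
#' standardized (mu, sigma) patches with the uncertainty-normalized loss,
#' layer 2 on layer 1's activation vectors with plain squared-error loss
#' (activations carry no sigma). Both layers use the L2 and KL penalties.
#'
#' @param patches a `patch_set` from [extract_patches()]/[bind_patches()].
#' @param config1,config2 [layer_config()]s; `config2`'s input size must be
#'   `config1$n_hidden`, and its loss is forced to `"squared_error"`.
#' @param maxit iteration cap per layer.
#' @param seeds integer pair of weight-initialization seeds.
#' @return list with elements `layer1` and `layer2`.
#' @export
stack_layers <- function(patches, config1, config2, maxit = 400L,
                         seeds = c(1L, 2L)) {
  check_that(config2$n_input == config1$n_hidden,
             "layer 2 input size must equal layer 1 hidden size")
  check_that(config2$loss == "squared_error",
             "layer 2 must use the squared_error loss")
  layer1 <- train_layer(patches, config1, maxit = maxit, seed = seeds[1])
  H1 <- encode(patches$mu, layer1)
  layer2 <- train_layer(H1, config2, maxit = maxit, seed = seeds[2])
  list(layer1 = layer1, layer2 = layer2)
}

#' Visualization data for learned features
#'
#' Layer-1 features can be displayed directly as the unit-normalized rows of
#' the encoder weight matrix (each row is a prototypical 30-day trajectory
#' element). Layer-2 features cannot, so each is represented by the `top_k`
#' input patches that activate it most strongly, sorted by descending
#' activation.
#'
#' @param layer1,layer2 trained `autoencoder_layer`s (`layer2` may be NULL).
#' @param patches `patch_set` used to rank layer-2 activations.
#' @param top_k patches kept per layer-2 feature (default 100).
#' @return list with `layer1_rows` (unit-norm rows) and `layer2_top`, a list
#'   per layer-2 feature of data.frames (patch index, activation).
#' @export
feature_panels <- function(layer1, layer2 = NULL, patches = NULL,
                           top_k = 100L) {
  rn <- sqrt(rowSums(layer1$W_enc^2))
  panel1 <- layer1$W_enc / pmax(rn, 1e-12)
  out <- list(layer1_rows = panel1, layer2_top = NULL)
  if (!is.null(layer2) && !is.null(patches)) {
    H1 <- encode(patches$mu, layer1)
    H2 <- encode(as.matrix(H1), layer2)
    H2 <- matrix(H2, nrow = layer2$config$n_hidden)
    out$layer2_top <- lapply(seq_len(nrow(H2)), function(j) {
      ord <- order(H2[j, ], decreasing = TRUE)[seq_len(min(top_k, ncol(H2)))]
      data.frame(patch = ord, activation = H2[j, ord])
    })
  }
  out
}
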