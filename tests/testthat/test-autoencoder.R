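test_that("patch extraction count, window and standardization follow the contract", {
  d <- toy_density(span_days = 365)
  ps <- extract_patches(d, rate = 50, window = 30, seed = 1)
  expect_equal(ncol(ps$mu), 50)           # 50 patches per 365 days of span
  expect_equal(nrow(ps$mu), 30)
  expect_equal(dim(ps$sigma), dim(ps$mu))
  expect_equal(colMeans(ps$mu), rep(0, 50), tolerance = 1e-10)
  expect_equal(apply(ps$mu, 2, sd), rep(1, 50), tolerance = 1e-10)
  expect_true(all(ps$sigma > 0))
  # per-patch sigma is scaled by the same patch sd
  k <- 7
  idx <- ps$start_day[k]:(ps$start_day[k] + 29)
  expect_equal(ps$sigma[, k], d$sigma[idx] / sd(d$mu[idx]), tolerance = 1e-12)
  expect_equal(ps$patch_mean[k], mean(d$mu[idx]))
})

test_that("patch count scales with span and short grids are skipped", {
  d2 <- toy_density(span_days = 2 * 365)
  expect_equal(ncol(extract_patches(d2, seed = 1)$mu), 100)
  d3 <- toy_density(span_days = 40)
  expect_equal(ncol(extract_patches(d3, seed = 1)$mu), max(1, round(50 * 40 / 365)))
  short <- toy_density(span_days = 10)
  expect_warning(ps <- extract_patches(short, window = 30), "shorter")
  expect_equal(ncol(ps$mu), 0)
})

test_that("patch extraction is deterministic and flat patches are dropped", {
  d <- toy_density()
  expect_identical(extract_patches(d, seed = 9), extract_patches(d, seed = 9))
  flat <- toy_density()
  flat$mu[] <- 1
  ps <- suppressWarnings(extract_patches(flat, seed = 1))
  expect_equal(ncol(ps$mu), 0)
  expect_equal(attr(ps, "n_dropped"), 50)
})

test_that("encode and decode match direct affine/sigmoid evaluation", {
  cfg <- layer_config(4, 3, beta = 0, lambda = 0)
  layer <- phenolearn:::init_layer(cfg, seed = 2)
  x <- c(0.3, -1, 2, 0.5)
  manual <- 1 / (1 + exp(-(layer$W_enc %*% x + layer$b_enc)))
  expect_equal(encode(x, layer), drop(manual), tolerance = 1e-12)
  h <- c(0.2, 0.8, 0.5)
  expect_equal(decode(h, layer), drop(layer$W_dec %*% h + layer$b_dec),
               tolerance = 1e-12)
  # zero weights and biases give sigmoid(0) = 0.5 everywhere
  layer0 <- layer
  layer0$W_enc[] <- 0; layer0$b_enc[] <- 0
  expect_equal(encode(x, layer0), rep(0.5, 3))
  # saturated bias drives the activation to 1
  layer0$b_enc[1] <- 50
  expect_equal(encode(x, layer0)[1], 1, tolerance = 1e-12)
  # h = 0 reconstructs the decoder bias
  expect_equal(decode(c(0, 0, 0), layer), layer$b_dec)
  expect_error(encode(c(1, 2), layer), "dimension")
  expect_error(decode(c(1, 2), layer), "dimension")
})

test_that("normalized squared error follows its definition and scaling law", {
  expect_equal(loss_normalized_squared_error(c(1, 0), c(1, 2), c(0, 0)), 0.5)
  expect_equal(loss_normalized_squared_error(c(1, 2), c(1, 1), c(1, 2)), 0)
  x <- rnorm(5); s <- runif(5, 0.5, 2); xh <- rnorm(5)
  expect_equal(loss_normalized_squared_error(x, 2 * s, xh),
               loss_normalized_squared_error(x, s, xh) / 4)
  expect_error(loss_normalized_squared_error(1, 0, 1), "positive")
})

test_that("KL sparsity divergence is non-negative and zero only at the target", {
  expect_equal(kl_sparsity(0.3, 0.3), 0)
  expect_equal(kl_sparsity(0.05, 0.5),
               0.05 * log(0.05 / 0.5) + 0.95 * log(0.95 / 0.5),
               tolerance = 1e-12)
  expect_equal(kl_sparsity(0.05, 0.5), 0.4946, tolerance = 1e-4)
  for (rh in c(0.01, 0.2, 0.9)) expect_gt(kl_sparsity(0.05, rh), 0)
  expect_error(kl_sparsity(0.05, 1.2), "strictly in")
})

test_that("total cost vanishes for a perfect unpenalized autoencoder", {
  # 2-hidden-unit layer on 1-D inputs can reconstruct exactly via the bias
  cfg <- layer_config(1, 2, beta = 0, lambda = 0, loss = "squared_error")
  layer <- phenolearn:::init_layer(cfg, seed = 1)
  layer$W_enc[] <- 0; layer$b_enc[] <- 0
  layer$W_dec[] <- 0
  X <- matrix(c(0.7, 0.7, 0.7), 1)
  layer$b_dec <- 0.7
  expect_equal(total_cost(X, NULL, layer)$cost, 0, tolerance = 1e-12)
  # L2 penalty strictly increases the cost for nonzero weights
  cfgL <- layer_config(1, 2, beta = 0, lambda = 0.1, loss = "squared_error")
  layerL <- layer; layerL$config <- cfgL
  layerL$W_dec[] <- 0.5
  rec_only <- total_cost(X, NULL, layer)$cost
  expect_gt(total_cost(X, NULL, layerL)$cost,
            rec_only + 0)
})

test_that("analytic gradients match central finite differences", {
  tb <- toy_patch_batch()
  for (loss in c("normalized_squared_error", "squared_error")) {
    for (tied in c(FALSE, TRUE)) {
      cfg <- layer_config(8, 5, rho = 0.05, beta = 1.2, lambda = 0.01,
                          loss = loss, tied = tied)
      layer <- phenolearn:::init_layer(cfg, seed = 3)
      theta <- phenolearn:::pack_params(layer)
      g <- total_cost(tb$X, tb$S, layer)$grad
      fd <- fd_gradient(tb$X, tb$S, cfg, theta)
      expect_lt(sqrt(sum((g - fd)^2)) / max(1, sqrt(sum(fd^2))), 1e-5)
    }
  }
})

test_that("inflating sigma reduces the normalized reconstruction cost", {
  tb <- toy_patch_batch()
  cfg <- layer_config(8, 5, beta = 0, lambda = 0)
  layer <- phenolearn:::init_layer(cfg, seed = 5)
  c0 <- total_cost(tb$X, tb$S, layer)$cost
  S_inflated <- tb$S
  S_inflated[1:4, ] <- S_inflated[1:4, ] * 10
  expect_lt(total_cost(tb$X, S_inflated, layer)$cost, c0)
})

test_that("training reduces the cost, is seeded-deterministic, and respects maxit = 0", {
  set.seed(8)
  # patches from a 1-D linear ramp family
  ramps <- vapply(runif(40, -2, 2), function(a) a * seq(-1, 1, length.out = 12),
                  numeric(12))
  X <- sweep(ramps, 2, colMeans(ramps))
  sds <- apply(X, 2, sd)
  X <- sweep(X, 2, pmax(sds, 1e-3), "/")
  S <- matrix(1, 12, 40)
  cfg <- layer_config(12, 10, beta = 0.5, lambda = 1e-4)
  l0 <- train_layer(X, cfg, S, maxit = 0, seed = 4)
  expect_equal(attr(l0, "cost_final"), attr(l0, "cost_initial"))
  expect_identical(l0$W_enc, phenolearn:::init_layer(cfg, 4)$W_enc)
  l1 <- train_layer(X, cfg, S, maxit = 150, seed = 4)
  expect_lte(attr(l1, "cost_final"), attr(l1, "cost_initial"))
  # reconstruction improves by at least half on the ramp family
  rec_cost <- function(layer) {
    H <- matrix(encode(X, layer), nrow = 10)
    sum((layer$W_dec %*% H + layer$b_dec - X)^2) / ncol(X)
  }
  expect_lt(rec_cost(l1), 0.5 * rec_cost(l0))
  l1b <- train_layer(X, cfg, S, maxit = 150, seed = 4)
  expect_identical(l1$W_enc, l1b$W_enc)
  expect_identical(l1$W_dec, l1b$W_dec)
})

test_that("the sparsity penalty moves average activations toward the target", {
  tb <- toy_patch_batch(n_input = 10, m = 60, seed = 13)
  cfg_no <- layer_config(10, 6, rho = 0.05, beta = 0, lambda = 1e-4)
  cfg_sp <- layer_config(10, 6, rho = 0.05, beta = 8, lambda = 1e-4)
  l_no <- train_layer(tb$X, cfg_no, tb$S, maxit = 200, seed = 2)
  l_sp <- train_layer(tb$X, cfg_sp, tb$S, maxit = 200, seed = 2)
  rho_hat <- function(l) rowMeans(matrix(encode(tb$X, l), nrow = 6))
  expect_lt(mean(abs(rho_hat(l_sp) - 0.05)), mean(abs(rho_hat(l_no) - 0.05)))
})

test_that("stacked layers chain dimensions and train bottom-up independently", {
  d <- toy_density()
  ps <- extract_patches(d, seed = 3)
  cfg1 <- layer_config(30, 9)
  cfg2 <- layer_config(9, 7, loss = "squared_error")
  st <- stack_layers(ps, cfg1, cfg2, maxit = 40, seeds = c(1, 2))
  expect_equal(st$layer2$config$n_input, cfg1$n_hidden)
  # retraining layer 2 with a new seed leaves layer 1 untouched
  st2 <- stack_layers(ps, cfg1, cfg2, maxit = 40, seeds = c(1, 9))
  expect_identical(st$layer1$W_enc, st2$layer1$W_enc)
  expect_false(identical(st$layer2$W_enc, st2$layer2$W_enc))
  expect_error(stack_layers(ps, cfg1, layer_config(8, 7, loss = "squared_error")),
               "input size")
  expect_error(stack_layers(ps, cfg1, layer_config(9, 7)), "squared_error")
})

test_that("feature panels normalize rows and rank top patches by activation", {
  d <- toy_density()
  ps <- extract_patches(d, seed = 3)
  st <- stack_layers(ps, layer_config(30, 6),
                     layer_config(6, 4, loss = "squared_error"), maxit = 30)
  fp <- feature_panels(st$layer1, st$layer2, ps, top_k = 10)
  expect_equal(sqrt(rowSums(fp$layer1_rows^2)), rep(1, 6), tolerance = 1e-10)
  expect_length(fp$layer2_top, 4)
  for (tt in fp$layer2_top) {
    expect_equal(nrow(tt), 10)
    expect_true(all(diff(tt$activation) <= 0))
  }
  # default keeps the top 100 patches per feature
  expect_equal(formals(feature_panels)$top_k, 100L)
})
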