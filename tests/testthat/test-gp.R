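test_that("interval warping matches direct evaluation", {
  # identity at a = b = 1
  t <- c(0, 2, 5.5, 9)
  expect_equal(warp_times(t, warp_config(1, 1)), t)
  # single interval [0, 4], a = 2, b = 0.5 -> 2 * 4^0.5 = 4
  expect_equal(warp_times(c(0, 4), warp_config(2, 0.5)), c(0, 4))
  # intervals 1, 4, 9 -> warped 2, 4, 6 -> cumulative 0, 2, 6, 12
  expect_equal(warp_times(c(0, 1, 5, 14), warp_config(2, 0.5)), c(0, 2, 6, 12))
  expect_error(warp_times(c(0, 3, 1)), "non-decreasing")
})

test_that("warp map agrees with warped times and extends piecewise", {
  t <- c(0, 4, 10)
  w <- warp_config(2, 0.5)
  wm <- warp_map(t, w)
  expect_equal(wm(t), warp_times(t, w))
  # identity warp is the identity map everywhere
  wid <- warp_map(t, warp_config(1, 1))
  tq <- seq(-3, 13, by = 0.7)
  expect_equal(wid(tq), tq)
  # midway in the length-4 interval: offset 2 * 2^0.5 from the interval start
  expect_equal(wm(2), 2 * sqrt(2))
  # strictly increasing, including beyond the observed range
  expect_true(all(diff(wm(seq(-5, 15, by = 0.25))) > 0))
})

test_that("with b < 1 long intervals are contracted relative to short ones", {
  w <- warp_config(10, 1 / 3)
  d <- c(0.5, 2, 10, 100, 1000)
  ratio <- (w$a * d^w$b) / d
  expect_true(all(diff(ratio) < 0))
})

test_that("covariance functions match their closed forms", {
  hp <- gp_hyperparameters(signal_sd = 1.3, length_scale = 4, alpha = 1,
                           noise_sd = 0.1)
  expect_equal(cov_squared_exponential(2, 2, hp), 1.3^2)
  expect_equal(cov_squared_exponential(0, 4, hp), 1.3^2 * exp(-0.5))
  expect_lt(cov_squared_exponential(0, 1e5, hp), 1e-12)
  expect_equal(cov_rational_quadratic(7, 7, hp), 1.3^2)
  hp1 <- gp_hyperparameters(1, 1, 1, 0.1)
  expect_equal(cov_rational_quadratic(0, 1, hp1), 1 / 1.5)
  # symmetry
  expect_equal(cov_rational_quadratic(1, 5, hp), cov_rational_quadratic(5, 1, hp))
  expect_error(gp_hyperparameters(signal_sd = -1), "positive")
})

test_that("log marginal likelihood matches the 1x1 closed form and is stationary", {
  hp <- gp_hyperparameters(0.9, 5, 1, 0.25)
  expect_equal(log_marginal_likelihood(0, 0, hp),
               -0.5 * log(2 * pi * (0.9^2 + 0.25^2)))
  s <- rand_gp_sequence(6, seed = 21)
  l0 <- log_marginal_likelihood(s$times, s$values, hp)
  l1 <- log_marginal_likelihood(s$times + 137.5, s$values, hp)
  expect_equal(l0, l1, tolerance = 1e-10)
})

test_that("analytic marginal-likelihood gradients match finite differences", {
  s <- rand_gp_sequence(7, seed = 31)
  for (kern in c("se", "rq")) {
    hp <- gp_hyperparameters(0.8, 8, 1.4, 0.3)
    g <- phenolearn:::lml_grad_log(s$times, s$values, hp, kern)
    nms <- names(g)
    fd <- vapply(nms, function(nm) {
      hp_p <- hp; hp_p[[nm]] <- hp[[nm]] * exp(1e-6)
      hp_m <- hp; hp_m[[nm]] <- hp[[nm]] * exp(-1e-6)
      (log_marginal_likelihood(s$times, s$values, hp_p, kern) -
         log_marginal_likelihood(s$times, s$values, hp_m, kern)) / 2e-6
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
  }
})

test_that("hyperparameter fitting never degrades the summed objective", {
  seqs <- lapply(1:5, function(i) rand_gp_sequence(8, seed = 40 + i))
  init <- gp_hyperparameters(1, 5, 1, 0.5)
  obj <- function(hp, kern) sum(vapply(seqs, function(s)
    log_marginal_likelihood(s$times, s$values, hp, kern), numeric(1)))
  for (kern in c("se", "rq")) {
    hp <- fit_hyperparameters(seqs, kern, init, maxit = 40)
    expect_gte(attr(hp, "objective"), obj(init, kern) - 1e-8)
    expect_equal(attr(hp, "objective"), obj(hp, kern), tolerance = 1e-8)
    # restarting at the fitted optimum changes the objective only negligibly
    hp2 <- fit_hyperparameters(seqs, kern, hp, maxit = 40)
    expect_lt(abs(attr(hp2, "objective") - attr(hp, "objective")),
              1e-4 * abs(attr(hp, "objective")) + 1e-6)
  }
})

test_that("the daily grid spans the observations with 15-day padding", {
  s <- obs_sequence("g", "gout", c(0, 3, 10), c(1, 2, 3))
  g <- make_grid(s)
  expect_length(g, 41)
  expect_equal(g[1], -15)
  expect_equal(g[41], 25)
  expect_true(all(diff(g) == 1))
  s2 <- obs_sequence("g2", "gout", c(0, 1e-4), c(1, 2))
  expect_length(make_grid(s2), 31)
})

test_that("posterior density matches the single-observation closed form", {
  hp <- gp_hyperparameters(1.2, 6, 1, 0.4)
  s2 <- 1.2^2; n2 <- 0.4^2; y <- 0.83
  s <- obs_sequence("one", "gout", c(0, 1e-9), c(y, y))
  # direct check through the conditioning oracle on a true 1-point system
  or <- gp_conditional_oracle(0, y, 0, hp)
  expect_equal(or$mu, y * s2 / (s2 + n2), tolerance = 1e-10)
  expect_equal(or$sigma^2, s2 + n2 - s2^2 / (s2 + n2), tolerance = 1e-10)
})

test_that("far from all observations the posterior reverts to the prior", {
  hp <- gp_hyperparameters(0.9, 3, 1, 0.2)
  s <- obs_sequence("far", "gout", c(0, 5, 9), c(1.5, -0.5, 1))
  d <- posterior_density(s, hp, "se", warp_config(1, 1), padding_days = 15)
  # the padded edge lies 5 length scales beyond the last observation
  edge <- length(d$grid_times)
  expect_lt(abs(d$mu[edge]), 1e-3)
  expect_equal(d$sigma[edge]^2, 0.9^2 + 0.2^2, tolerance = 1e-3)
})

test_that("predictive variance never exceeds the prior predictive variance", {
  hp <- gp_hyperparameters(1.1, 7, 1.3, 0.3)
  for (i in 1:20) {
    s <- rand_gp_sequence(sample(2:10, 1), seed = 100 + i)
    seq_ <- obs_sequence(paste0("s", i), "unlabeled", s$times, s$values + 10)
    seq_$values <- seq_$values - 10   # allow negatives post-standardization
    d <- posterior_density(seq_, hp, "rq", warp_config(1, 1))
    expect_true(all(d$sigma^2 <= hp$signal_sd^2 + hp$noise_sd^2 + 1e-10))
    expect_true(all(d$sigma > 0))
  }
})

test_that("noise-free posterior interpolates the observations", {
  hp <- gp_hyperparameters(1, 5, 1, 1e-6)
  s <- obs_sequence("interp", "gout", c(0, 4, 8), c(0.5, -1, 0.25))
  d <- posterior_density(s, hp, "rq", warp_config(1, 1))
  at_obs <- d$grid_times %in% s$times
  expect_equal(d$mu[at_obs], s$values, tolerance = 1e-4)
})

test_that("kernel comparison reports one fitted row per candidate", {
  seqs <- lapply(1:4, function(i) rand_gp_sequence(6, seed = 60 + i))
  cmp <- compare_kernels(seqs, c("se", "rq"), maxit = 15)
  expect_identical(cmp$kernel, c("se", "rq"))
  expect_true(all(is.finite(cmp$objective)))
  expect_true(is.na(cmp$alpha[1]) && is.finite(cmp$alpha[2]))
})
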