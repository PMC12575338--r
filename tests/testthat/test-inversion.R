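test_that("prediction is self-consistent and channel-local", {
  drv <- test_driver(2, duration = 2)
  p <- gen_params(delta_a = 0.5, delta_k = 0, obs_noise_sd = 0)
  ref <- observe_latent(simulate_latent(drv, p), p)
  pred <- predict_observed(p, NULL, drv)
  expect_equal(pred$h_mu, ref$h_mu)
  expect_equal(pred$h_M, ref$h_M)

  # free-value overrides reproduce the same path
  base <- gen_params(delta_a = 0, delta_k = 0, obs_noise_sd = 0)
  pred2 <- predict_observed(base, c(delta_a = 0.5, delta_k = 0), drv)
  expect_equal(pred2$h_M, ref$h_M)

  # delta_a and delta_k act on the macro channel only
  p0 <- predict_observed(base, NULL, drv)
  pa <- predict_observed(base, c(delta_a = 0.4), drv)
  pk <- predict_observed(base, c(delta_k = 0.4), drv)
  expect_equal(pa$h_mu, p0$h_mu)
  expect_equal(pk$h_mu, p0$h_mu)
  expect_gt(max(abs(pa$h_M - p0$h_M)), 1e-3)
  expect_gt(max(abs(pk$h_M - p0$h_M)), 1e-3)
})

test_that("log-likelihood matches Gaussian closed forms and degenerate limits", {
  drv <- test_driver(3, duration = 1)
  p <- gen_params(obs_noise_sd = 0)
  noisefree <- observe_latent(simulate_latent(drv, p), p)
  lambda <- 37.5
  n <- nrow(noisefree)

  # zero residuals: (2T/2) * ln(lambda / 2pi)
  ll0 <- pair_loglik(NULL, noisefree, p, drv, noise_spec("none"),
                     obs_precision = lambda)
  expect_equal(as.numeric(ll0), n * log(lambda / (2 * pi)), tolerance = 1e-8)

  # additive mode with zero volatility equals the deterministic value exactly
  p_noisy <- gen_params(obs_noise_sd = 0.05)
  dat <- observe_latent(simulate_latent(drv, p_noisy), p_noisy, seed = 8)
  ll_none <- pair_loglik(NULL, dat, gen_params(sigma_mu = 0, sigma_M = 0),
                         drv, noise_spec("none"), obs_precision = 400)
  ll_add <- pair_loglik(NULL, dat, gen_params(sigma_mu = 0, sigma_M = 0),
                        drv, noise_spec("additive"), obs_precision = 400)
  expect_identical(as.numeric(ll_none), as.numeric(ll_add))

  expect_error(pair_loglik(NULL, dat, p, drv, obs_precision = -1),
               "positive")
})

test_that("EKF likelihood matches an independent Kalman filter on the linearized system", {
  # near-linear observers: k so small that tanh is linear to ~1e-13
  dt <- 0.004
  n <- 300
  drv <- const_driver(0.8, fs = 250, duration = n * dt)
  p <- gen_params(a = -1, b = 1, c = 1, k = 1e-4, delta_a = 0.3,
                  delta_k = 2e-5, sigma_mu = 0.3, sigma_M = 0.2,
                  obs_noise_sd = 1e-4)
  lat <- simulate_latent(drv, p, noise_spec("additive", seed = 21))
  obs <- observe_latent(lat, p, seed = 22)
  r_var <- 1e-8
  ll_ekf <- pair_loglik(NULL, obs, p, drv, noise_spec("additive"),
                        obs_precision = 1 / r_var)
  Q <- outer(c(p$sigma_mu, p$sigma_M), c(p$sigma_mu, p$sigma_M))
  ll_kf <- kf_oracle_loglik(cbind(obs$h_mu, obs$h_M), lat$u, dt,
                            p$a, p$a + p$delta_a, p$b,
                            p$c * p$k, p$c * (p$k + p$delta_k), Q, r_var)
  expect_lt(abs(as.numeric(ll_ekf) - ll_kf), 1e-6)

  # independent-increment mode: diagonal process noise covariance
  ll_ekf_ind <- pair_loglik(NULL, obs, p, drv,
                            noise_spec("additive", shared_increments = FALSE),
                            obs_precision = 1 / r_var)
  ll_kf_ind <- kf_oracle_loglik(cbind(obs$h_mu, obs$h_M), lat$u, dt,
                                p$a, p$a + p$delta_a, p$b,
                                p$c * p$k, p$c * (p$k + p$delta_k),
                                diag(c(p$sigma_mu^2, p$sigma_M^2)), r_var)
  expect_lt(abs(as.numeric(ll_ekf_ind) - ll_kf_ind), 1e-6)
})

test_that("variational Laplace reproduces conjugate linear-Gaussian results", {
  set.seed(42)
  n <- 30
  X <- cbind(rnorm(n), rnorm(n))
  sigma <- 0.5
  theta_true <- c(0.8, -0.4)
  y <- as.numeric(X %*% theta_true) + rnorm(n, sd = sigma)
  m0 <- c(0, 0)
  S0 <- diag(c(1, 2))
  prior <- belief(c("b1", "b2"), m0, S0)
  objective <- function(v) {
    sum(dnorm(y, as.numeric(X %*% unname(v)), sigma, log = TRUE))
  }
  fit <- laplace_fit(objective, prior)
  oracle <- lg_posterior(y, X, m0, S0, sigma)
  expect_equal(unname(fit$mean), oracle$mean, tolerance = 1e-6)
  expect_equal(unname(fit$cov), unname(oracle$cov), tolerance = 1e-6)
  expect_lt(abs(fit$free_energy - lg_evidence(y, X, m0, S0, sigma)), 1e-4)
})

test_that("free energy is monotone, complexity non-negative, labels permute", {
  dat <- make_dataset("identical_observers", seed = 5, duration = 1)
  res <- fit_and_compare(dat$observed, dat$driver)
  expect_true(all(diff(res$fit$f_trace) >= 0))
  expect_gte(res$fit$complexity, 0)
  expect_equal(res$fit$accuracy - res$fit$complexity, res$fit$free_energy)

  # covariance is symmetric positive-definite
  ev <- eigen(res$fit$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))

  # permuting the prior labels permutes the posterior consistently
  s <- inversion_settings()
  pr1 <- default_prior(s)
  perm <- c("delta_k", "delta_a", "log_precision")
  i <- match(perm, pr1$names)
  pr2 <- belief(perm, pr1$mean[i], pr1$cov[i, i])
  f1 <- suppressWarnings(fit_pair(dat$observed, gen_params(), dat$driver,
                                  noise_spec("none"), pr1, s))
  f2 <- suppressWarnings(fit_pair(dat$observed, gen_params(), dat$driver,
                                  noise_spec("none"), pr2, s))
  expect_equal(f2$mean[pr1$names], f1$mean[pr1$names], tolerance = 1e-5)
  expect_equal(f2$cov[pr1$names, pr1$names], f1$cov[pr1$names, pr1$names],
               tolerance = 1e-4)
  expect_equal(f1$free_energy, f2$free_energy, tolerance = 1e-3)
})

test_that("posterior recovers the truth at vanishing noise", {
  dat <- make_dataset("identical_observers", seed = 6, effect = 0,
                      obs_noise_sd = 0.01, duration = 2)
  fit <- fit_and_compare(dat$observed, dat$driver)$fit
  td <- tidy(fit)
  for (par in c("delta_a", "delta_k")) {
    row <- td[td$term == par, ]
    expect_lt(abs(row$estimate), 3 * row$std.error)
  }
})
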