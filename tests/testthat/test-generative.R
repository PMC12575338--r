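test_that("deterministic integration matches linear ODE closed forms", {
  p <- gen_params(a = -1, b = 0, sigma_mu = 0, sigma_M = 0, obs_noise_sd = 0)

  # zero input, zero initial state: stays at the fixed point
  lat0 <- simulate_latent(const_driver(0, duration = 2), p)
  expect_equal(lat0$x_mu, rep(0, nrow(lat0)))
  expect_equal(lat0$x_M, rep(0, nrow(lat0)))

  # x(0) = 1 decays as exp(-t); second-order global accuracy
  err_at <- function(dt) {
    drv <- const_driver(0, fs = 1 / dt, duration = 1 + dt)
    lat <- simulate_latent(drv, p, dt = dt, x0 = c(1, 1))
    abs(lat$x_mu[nrow(lat)] - exp(-lat$time[nrow(lat)]))
  }
  e1 <- err_at(0.01)
  e2 <- err_at(0.005)
  expect_lt(e1, 1e-4)
  order <- log2(e1 / e2)
  expect_gt(order, 1.7)
  expect_lt(order, 2.3)
})

test_that("multiplicative Stratonovich solution has the exact log-normal law", {
  # dx = sigma x o dW with x(0) = 1 has solution x(t) = exp(sigma W(t)),
  # so ln x(1) ~ N(0, sigma^2). Oracle: direct sampling of W(1) ~ N(0,1).
  sigma <- 0.5
  p <- suppressWarnings(gen_params(a = 0, b = 0, sigma_mu = sigma,
                                   sigma_M = sigma, obs_noise_sd = 0))
  drv <- const_driver(0, fs = 250, duration = 1)
  n_rep <- 2000
  lnx <- vapply(seq_len(n_rep), function(i) {
    lat <- simulate_latent(drv, p, noise_spec("multiplicative", seed = i),
                           x0 = c(1, 1))
    log(lat$x_mu[nrow(lat)])
  }, numeric(1))
  se_mean <- sigma / sqrt(n_rep)
  expect_lt(abs(mean(lnx)), 3 * se_mean)
  se_var <- sigma^2 * sqrt(2 / (n_rep - 1))
  expect_lt(abs(var(lnx) - sigma^2), 3 * se_var)
  ks <- suppressWarnings(stats::ks.test(lnx, "pnorm", 0, sigma))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulation is seed-deterministic and shared noise collapses identical models", {
  p <- gen_params(delta_a = 0, delta_k = 0, obs_noise_sd = 0)
  drv <- test_driver(3)
  a <- simulate_latent(drv, p, noise_spec("additive", seed = 11))
  b <- simulate_latent(drv, p, noise_spec("additive", seed = 11))
  expect_identical(a$x_mu, b$x_mu)
  expect_identical(a$x_M, b$x_M)

  # same dynamics + same observers + one Wiener path => identical channels
  obs <- observe_latent(a, p)
  expect_equal(obs$h_mu, obs$h_M)

  # independent increments break the identity
  ind <- simulate_latent(drv, p, noise_spec("additive",
                                            shared_increments = FALSE,
                                            seed = 11))
  expect_gt(max(abs(ind$x_mu - ind$x_M)), 1e-3)
})

test_that("divergence and argument errors are reported", {
  p <- suppressWarnings(gen_params(a = 5, b = 1, sigma_mu = 0, sigma_M = 0))
  expect_error(simulate_latent(const_driver(1, duration = 4), p),
               "divergence at step")
  expect_error(simulate_latent(const_driver(0), gen_params(), dt = -0.1),
               "`dt` must be")
})

test_that("observer mapping saturates, linearizes, and is bounded by c", {
  drv <- test_driver(4, duration = 2)
  p <- gen_params(c = 2, k = 0.5, obs_noise_sd = 0)
  lat <- simulate_latent(drv, p)

  # tanh(0) = 0
  lat0 <- simulate_latent(const_driver(0, duration = 1), p)
  obs0 <- observe_latent(lat0, p)
  expect_equal(obs0$h_mu, rep(0, nrow(obs0)))
  expect_equal(obs0$h_M, rep(0, nrow(obs0)))

  # saturation: |h| < c everywhere
  obs <- observe_latent(lat, p)
  expect_true(all(abs(obs$h_mu) < p$c))
  expect_true(all(abs(obs$h_M) < p$c))

  # small-signal linearization h ~ c k x
  lat$x_mu <- rep(0.01, nrow(lat))
  lat$x_M <- rep(0.01, nrow(lat))
  obs_lin <- observe_latent(lat, p)
  expect_true(all(abs(obs_lin$h_mu / (p$c * p$k * 0.01) - 1) < 1e-4))

  # observation noise is seeded and independent across channels
  pn <- gen_params(obs_noise_sd = 0.1)
  o1 <- observe_latent(lat, pn, seed = 5)
  o2 <- observe_latent(lat, pn, seed = 5)
  expect_identical(o1$h_mu, o2$h_mu)
  expect_gt(stats::sd(o1$h_mu - o1$h_M), 0.05)
})

test_that("reduced models zero exactly one deviation parameter", {
  full <- gen_params(delta_a = 0.5, delta_k = 0.3)
  io <- reduce_params(full, "identical_observers")
  expect_equal(io$delta_k, 0)
  expect_equal(io$delta_a, 0.5)
  is <- reduce_params(full, "identical_systems")
  expect_equal(is$delta_a, 0)
  expect_equal(is$delta_k, 0.3)
  none <- gen_params(delta_a = 0, delta_k = 0)
  expect_equal(unclass(reduce_params(none, "identical_observers")),
               unclass(none))
  expect_error(reduce_params(full, "nonsense"))
})

test_that("difference decomposition isolates observer-only noise terms", {
  drv <- test_driver(6)

  # identical systems and observers, equal volatility, one path: both zero
  p_eq <- gen_params(delta_a = 0, delta_k = 0, sigma_mu = 0.2, sigma_M = 0.2,
                     obs_noise_sd = 0)
  lat_eq <- simulate_latent(drv, p_eq, noise_spec("additive", seed = 2))
  st_eq <- stratonovich_terms(lat_eq, p_eq)
  expect_equal(max(abs(st_eq$degenerate)), 0)
  expect_equal(max(abs(st_eq$observer_only)), 0)

  # unequal volatilities, shared path: exact identities at t = 0
  p_sig <- gen_params(delta_a = 0, delta_k = 0, sigma_mu = 0.3,
                      sigma_M = 0.1, obs_noise_sd = 0)
  lat_sig <- simulate_latent(drv, p_sig, noise_spec("additive", seed = 3))
  st_sig <- stratonovich_terms(lat_sig, p_sig)
  dt <- diff(lat_sig$time[1:2])
  xi0 <- attr(lat_sig, "dw")$mu[1] / dt
  expect_equal(st_sig$degenerate[1], 0)
  expect_equal(st_sig$observer_only[1],
               (0.3 - 0.1) * xi0 * p_sig$c * p_sig$k)

  # generic stochastic run: terms reconstruct the finite-difference
  # derivative of the noise-free observed difference
  p_gen <- gen_params(delta_a = 0.5, delta_k = 0.3, sigma_mu = 0.25,
                      sigma_M = 0.15, obs_noise_sd = 0)
  lat <- simulate_latent(drv, p_gen, noise_spec("additive", seed = 4))
  obs <- observe_latent(lat, p_gen)
  st <- stratonovich_terms(lat, p_gen)
  d_fd <- diff(obs$h_mu - obs$h_M) / dt
  resid <- d_fd - (st$degenerate + st$observer_only)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(resid), 10 * dt * rms(d_fd))

  # deterministic trajectories have a null observer-only term
  lat_d <- simulate_latent(drv, p_gen, noise_spec("none"))
  st_d <- stratonovich_terms(lat_d, p_gen)
  expect_equal(max(abs(st_d$observer_only)), 0)
})
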