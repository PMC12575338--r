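# Shared fixtures and independent oracle implementations.

withr_like_tempdir <- function(stem) {
  d <- file.path(tempdir(), paste0("sysobs-", stem))
  unlink(d, recursive = TRUE)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

const_driver <- function(value = 0, fs = 250, duration = 4) {
  n <- round(fs * duration)
  as_driver(tibble::tibble(time = (seq_len(n) - 1) / fs,
                           value = rep(value, n)))
}

test_driver <- function(seed = 1, fs = 250, duration = 4, n_scenes = 8) {
  b <- random_scene_boundaries(n_scenes, duration,
                               seed = derive_seed(seed, 1), fs = fs)
  drv <- scene_driver(b, fs = fs, duration = duration,
                      seed = derive_seed(seed, 2))
  add_fluctuations(drv, noise_sd = 0.1, smooth_width = 0.05,
                   seed = derive_seed(seed, 3))
}

# ground-truth dataset from one of the two reduced models
make_dataset <- function(scenario = c("identical_observers",
                                      "identical_systems"),
                         seed = 1, mode = "none", effect = 0.5,
                         duration = 4, obs_noise_sd = 0.05, shared = TRUE,
                         sigma = 0.2) {
  scenario <- match.arg(scenario)
  drv <- test_driver(derive_seed(seed, 10), duration = duration)
  p <- gen_params(obs_noise_sd = obs_noise_sd, sigma_mu = sigma,
                  sigma_M = sigma)
  if (scenario == "identical_observers") {
    p$delta_a <- effect
  } else {
    p$delta_k <- effect
  }
  lat <- simulate_latent(drv, p, noise_spec(mode, shared_increments = shared,
                                            seed = derive_seed(seed, 20)))
  obs <- observe_latent(lat, p, seed = derive_seed(seed, 30))
  list(driver = drv, latent = lat, observed = obs, truth = p)
}

# full-model inversion followed by reduction to both candidate models
fit_and_compare <- function(observed, driver, mode = "none",
                            params = gen_params(),
                            settings = inversion_settings()) {
  prior <- default_prior(settings)
  fit <- suppressWarnings(
    fit_pair(observed, params, driver, noise_spec(mode), prior, settings)
  )
  io <- model_reduction(fit, prior, pin_parameter(prior, "delta_k"))
  is <- model_reduction(fit, prior, pin_parameter(prior, "delta_a"))
  f <- c(identical_observers = io$reduced_posterior$free_energy,
         identical_systems = is$reduced_posterior$free_energy)
  list(fit = fit, f = f, comparison = model_probabilities(f))
}

# Oracle 1: textbook discrete Kalman filter on the linearized system,
# written independently with plain matrix algebra.
kf_oracle_loglik <- function(y, u, dt, a1, a2, b, g1, g2, Q, r_var) {
  Fm <- diag(c(1 + a1 * dt + (a1 * dt)^2 / 2,
               1 + a2 * dt + (a2 * dt)^2 / 2))
  A <- diag(c(a1, a2))
  H <- diag(c(g1, g2))
  R <- diag(r_var, 2)
  m <- c(0, 0)
  P <- matrix(0, 2, 2)
  ll <- 0
  for (i in seq_len(nrow(y))) {
    if (i > 1) {
      inp <- (dt / 2) * b * (u[i - 1] + u[i]) * c(1, 1) +
        (dt^2 / 2) * as.numeric(A %*% (b * u[i - 1] * c(1, 1)))
      m <- as.numeric(Fm %*% m) + inp
      P <- Fm %*% P %*% t(Fm) + Q * dt
    }
    S <- H %*% P %*% t(H) + R
    e <- y[i, ] - as.numeric(H %*% m)
    ll <- ll - log(2 * pi) -
      0.5 * as.numeric(determinant(S, logarithm = TRUE)$modulus) -
      0.5 * sum(e * solve(S, e))
    K <- P %*% t(H) %*% solve(S)
    m <- m + as.numeric(K %*% e)
    P <- (diag(2) - K %*% H) %*% P
  }
  ll
}

# Oracle 2: closed-form Bayesian linear regression (conjugate Gaussian).
lg_posterior <- function(y, X, m0, S0, sigma) {
  S0i <- solve(S0)
  Sn <- solve(S0i + crossprod(X) / sigma^2)
  mn <- as.numeric(Sn %*% (S0i %*% m0 + crossprod(X, y) / sigma^2))
  list(mean = mn, cov = Sn)
}

lg_evidence <- function(y, X, m0, S0, sigma) {
  n <- length(y)
  C <- sigma^2 * diag(n) + X %*% S0 %*% t(X)
  mu <- as.numeric(X %*% m0)
  -0.5 * n * log(2 * pi) -
    0.5 * as.numeric(determinant(C, logarithm = TRUE)$modulus) -
    0.5 * sum((y - mu) * solve(C, y - mu))
}
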