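test_that("pinning collapses one parameter and is idempotent", {
  pr <- belief(c("delta_a", "delta_k"), c(0, 0), diag(2))
  pinned <- pin_parameter(pr, "delta_a")
  expect_equal(unname(pinned$cov), diag(c(0, 1)))
  expect_equal(unname(pinned$mean), c(0, 0))
  expect_equal(pin_parameter(pinned, "delta_a"), pinned)
  # pinning both yields a fully degenerate prior (allowed)
  both <- pin_parameter(pinned, "delta_k")
  expect_equal(unname(both$cov), matrix(0, 2, 2))
  expect_error(pin_parameter(pr, "nope"), "unknown parameter")
})

test_that("model reduction: null reduction and the Savage-Dickey closed form", {
  prior <- belief("theta", 0, matrix(1))
  post <- belief("theta", 1, matrix(0.5), free_energy = -10)

  # reduced prior identical to the prior: no evidence change
  null <- model_reduction(post, prior, prior)
  expect_equal(null$delta_f, 0, tolerance = 1e-12)
  expect_equal(unname(null$reduced_posterior$mean), 1, tolerance = 1e-10)
  expect_equal(unname(null$reduced_posterior$cov[1, 1]), 0.5,
               tolerance = 1e-10)

  # pin to zero: log ratio of posterior to prior density at zero
  sd_expected <- dnorm(0, 1, sqrt(0.5), log = TRUE) - dnorm(0, 0, 1, log = TRUE)
  red <- model_reduction(post, prior, pin_parameter(prior, "theta"))
  expect_equal(red$delta_f, sd_expected, tolerance = 1e-12)
  expect_equal(red$delta_f, -0.6534264, tolerance = 1e-6)
  expect_equal(red$reduced_posterior$free_energy, -10 + sd_expected)
})

test_that("Savage-Dickey reduction matches pinned-prior re-inversion", {
  # conjugate linear-Gaussian case: equality to 1e-3 nats
  set.seed(7)
  n <- 40
  X <- cbind(rnorm(n), rnorm(n))
  sigma <- 0.4
  y <- as.numeric(X %*% c(0.25, -0.15)) + rnorm(n, sd = sigma)
  prior <- belief(c("b1", "b2"), c(0, 0), diag(2))
  obj_full <- function(v) sum(dnorm(y, as.numeric(X %*% unname(v)), sigma,
                                    log = TRUE))
  fit_full <- laplace_fit(obj_full, prior)
  red <- model_reduction(fit_full, prior, pin_parameter(prior, "b1"))
  prior1 <- belief("b2", 0, matrix(1))
  obj_red <- function(v) sum(dnorm(y, X[, 2] * unname(v), sigma, log = TRUE))
  fit_red <- laplace_fit(obj_red, prior1)
  expect_lt(abs(red$reduced_posterior$free_energy - fit_red$free_energy),
            1e-3)

  # weakly nonlinear state-space case: agreement to 0.1 nats
  dat <- make_dataset("identical_observers", seed = 9, effect = 0.2,
                      duration = 1, obs_noise_sd = 0.05)
  s <- inversion_settings()
  prior_f <- default_prior(s)
  fit <- suppressWarnings(fit_pair(dat$observed, gen_params(), dat$driver,
                                   noise_spec("none"), prior_f, s))
  red2 <- model_reduction(fit, prior_f, pin_parameter(prior_f, "delta_a"))
  prior_r <- belief(c("delta_k", "log_precision"), c(0, 2), diag(c(1, 4)))
  base <- gen_params(delta_a = 0, delta_k = 0)
  fit_r <- suppressWarnings(fit_pair(dat$observed, base, dat$driver,
                                     noise_spec("none"), prior_r, s))
  expect_lt(abs(red2$reduced_posterior$free_energy - fit_r$free_energy), 0.1)
})

test_that("reduced posterior equals the conditional of the full posterior", {
  mu <- c(0.6, -0.2, 1.5)
  S <- matrix(c(0.30, 0.05, 0.02,
                0.05, 0.20, -0.03,
                0.02, -0.03, 0.50), 3, 3)
  post <- belief(c("delta_a", "delta_k", "log_precision"), mu, S,
                 free_energy = 0)
  prior <- belief(post$names, c(0, 0, 2), diag(c(1, 1, 4)))
  red <- model_reduction(post, prior, pin_parameter(prior, "delta_a"))
  # conditional moments computed directly from the joint Gaussian
  cond_mean <- mu[2:3] + S[2:3, 1] / S[1, 1] * (0 - mu[1])
  cond_cov <- S[2:3, 2:3] - tcrossprod(S[2:3, 1]) / S[1, 1]
  expect_equal(unname(red$reduced_posterior$mean[2:3]), cond_mean,
               tolerance = 1e-10)
  expect_equal(unname(red$reduced_posterior$cov[2:3, 2:3]), cond_cov,
               tolerance = 1e-10)
  expect_equal(unname(red$reduced_posterior$mean[1]), 0)
  expect_equal(unname(red$reduced_posterior$cov[1, ]), c(0, 0, 0))
})

test_that("model probabilities are a shift-invariant softmax with correct limits", {
  eq <- model_probabilities(c(m1 = 0, m2 = 0))
  expect_equal(eq$probability, c(0.5, 0.5))

  p19 <- model_probabilities(c(a = log(19), b = 0))
  expect_equal(p19$probability, c(0.95, 0.05), tolerance = 1e-12)

  p3 <- model_probabilities(c(a = 3, b = 0))
  expect_equal(p3$probability[2], 1 / (1 + exp(3)), tolerance = 1e-12)

  shifted <- model_probabilities(c(a = 3 + 123.4, b = 0 + 123.4))
  expect_equal(shifted$probability, p3$probability, tolerance = 1e-12)
  expect_equal(shifted$free_energy, p3$free_energy)

  expect_equal(attr(p3, "winner"), "a")
  expect_equal(attr(p3, "losing_probability"), 1 / (1 + exp(3)),
               tolerance = 1e-12)
  expect_equal(sum(p3$probability), 1, tolerance = 1e-12)
  expect_equal(min(p3$free_energy), 0)

  expect_error(model_probabilities(c(a = Inf, b = 0)), "finite")
  expect_error(model_probabilities(c(a = 1)), "at least two")
})
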