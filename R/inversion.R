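#' Inversion settings
#'
#' Controls for the variational-Laplace optimizer.
#'
#' @param max_iterations Maximum number of Gauss-Newton iterations.
#' @param f_tolerance Convergence tolerance in nats: the fit stops once the
#'   free-energy change of accepted steps stays below this on three
#'   consecutive iterations.
#' @param damping_init Initial Levenberg-Marquardt damping; halved after an
#'   accepted step, doubled after a rejected one.
#' @param estimate_obs_precision If `TRUE` (default) one shared
#'   log-observation-precision hyperparameter is estimated jointly with the
#'   deviation parameters.
#' @param log_precision_prior Length-2 numeric `(mean, variance)` of the
#'   Gaussian hyperprior on the log observation precision, in nats.
#' @param fd_step Central finite-difference step for gradients and curvature.
#' @return An object of class `sysobs_settings`.
#' @export
inversion_settings <- function(max_iterations = 64, f_tolerance = 1e-3,
                               damping_init = 1e-4,
                               estimate_obs_precision = TRUE,
                               log_precision_prior = c(mean = 2, variance = 4),
                               fd_step = 1e-4) {
  stopifnot(max_iterations >= 1, f_tolerance > 0, damping_init > 0,
            length(log_precision_prior) == 2, log_precision_prior[2] > 0,
            fd_step > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 f_tolerance = f_tolerance, damping_init = damping_init,
                 estimate_obs_precision = isTRUE(estimate_obs_precision),
                 log_precision_prior = unname(log_precision_prior),
                 fd_step = fd_step),
            class = "sysobs_settings")
}

#' Gaussian belief over named parameters
#'
#' The common container for priors and posteriors: an ordered set of
#' parameter labels, a mean vector, a covariance matrix, and (for posteriors)
#' a variational free energy in nats.
#'
#' @param names Character vector of parameter labels.
#' @param mean Numeric mean vector.
#' @param cov Covariance matrix; must be symmetric (within 1e-10) with
#'   eigenvalues above -1e-10. It is symmetrized on construction.
#' @param free_energy Optional free energy (nats); `NULL` for priors.
#' @return An object of class `sysobs_belief`.
#' @export
#' @examples
#' belief(c("delta_a", "delta_k"), c(0, 0), diag(2))
belief <- function(names, mean, cov, free_energy = NULL) {
  names <- as.character(names)
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  d <- length(names)
  stopifnot(length(mean) == d, all(dim(cov) == d))
  if (max(abs(cov - t(cov))) > 1e-10) {
    stop("covariance must be symmetric within 1e-10", call. = FALSE)
  }
  cov <- (cov + t(cov)) / 2
  if (d > 0) {
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-10)) {
      stop("covariance has eigenvalues below -1e-10", call. = FALSE)
    }
  }
  dimnames(cov) <- list(names, names)
  structure(list(names = names, mean = stats::setNames(mean, names),
                 cov = cov, free_energy = free_energy),
            class = "sysobs_belief")
}

#' @export
print.sysobs_belief <- function(x, ...) {
  cat(sprintf("<%s> %d parameter(s)\n", class(x)[1], length(x$names)))
  sds <- sqrt(pmax(diag(x$cov), 0))
  for (i in seq_along(x$names)) {
    cat(sprintf("  %-14s %8.4f (sd %.4f)\n", x$names[i], x$mean[i], sds[i]))
  }
  if (!is.null(x$free_energy)) {
    cat(sprintf("  free energy: %.3f nats\n", x$free_energy))
  }
  invisible(x)
}

#' Default prior over the deviation parameters
#'
#' Standard normal (mean zero, unit variance) priors on `delta_a` and
#' `delta_k`, plus the log-precision hyperprior when observation precision is
#' estimated.
#'
#' @param settings An [inversion_settings()] object.
#' @return A `sysobs_belief`.
#' @export
default_prior <- function(settings = inversion_settings()) {
  if (settings$estimate_obs_precision) {
    belief(c("delta_a", "delta_k", "log_precision"),
           c(0, 0, settings$log_precision_prior[1]),
           diag(c(1, 1, settings$log_precision_prior[2])))
  } else {
    belief(c("delta_a", "delta_k"), c(0, 0), diag(2))
  }
}

apply_free_values <- function(params, free_values) {
  if (!is.null(free_values)) {
    for (nm in intersect(names(free_values), c("delta_a", "delta_k"))) {
      params[[nm]] <- as.numeric(free_values[[nm]])
    }
  }
  params
}

#' Mean prediction of the observed pair
#'
#' Deterministic forward prediction used as the likelihood mean: the
#' noise-free simulation passed through the noise-free observers. For
#' multiplicative state noise the latent mean follows the Ito-corrected
#' drift rate \eqn{a + \sigma^2/2} (the mean of the Stratonovich solution);
#' for additive noise the mean path is the deterministic solution. Process
#' noise enters the likelihood through [pair_loglik()], not the prediction.
#'
#' @param params A [gen_params()] object.
#' @param free_values Named scalars overriding `delta_a` and/or `delta_k`.
#' @param driver A `sysobs_driver`.
#' @param noise A [noise_spec()] (only the mode matters here).
#' @param dt Integration step; defaults to the driver interval.
#' @return A `sysobs_observed` containing the predicted mean channels.
#' @export
predict_observed <- function(params, free_values = NULL, driver,
                             noise = noise_spec("none"), dt = NULL) {
  params <- apply_free_values(params, free_values)
  p_mean <- params
  if (noise$mode == "multiplicative") {
    p_mean$a <- params$a + params$sigma_mu^2 / 2
    p_mean$delta_a <- (params$a + params$delta_a + params$sigma_M^2 / 2) -
      p_mean$a
  }
  p_mean$obs_noise_sd <- 0
  lat <- simulate_latent(driver, p_mean, noise_spec("none"), dt = dt)
  observe_latent(lat, p_mean)
}

#' Prediction-error log-likelihood of an observed pair
#'
#' For `mode = "none"` this is the independent-Gaussian log density of the
#' residuals between the observed channels and the deterministic prediction,
#' at observation precision `obs_precision`. For additive or multiplicative
#' state noise it is the prediction-error decomposition of a
#' continuous-discrete extended Kalman filter: Heun mean propagation,
#' linearized covariance propagation with process-noise intensity
#' \eqn{\sigma^2} (or \eqn{\sigma^2 x^2}), observation Jacobian
#' \eqn{c\,k\,\mathrm{sech}^2(kx)}, and cross-channel process-noise
#' correlation when increments are shared. Both channels contribute; the
#' result is deterministic given its inputs.
#'
#' @param free_values Named scalars overriding `delta_a` and/or `delta_k`.
#' @param observed A `sysobs_observed`.
#' @param params A [gen_params()] object.
#' @param driver A `sysobs_driver` aligned with the observation grid.
#' @param noise A [noise_spec()].
#' @param obs_precision Observation precision (1 / signal variance); must be
#'   positive. Defaults to `1 / obs_noise_sd^2` from `params`.
#' @return Log likelihood in nats, with attribute `repairs` counting
#'   covariance positive-definiteness repairs (clipping at 1e-12).
#' @export
pair_loglik <- function(free_values = NULL, observed, params, driver,
                        noise = noise_spec("none"),
                        obs_precision = 1 / params$obs_noise_sd^2) {
  stopifnot(inherits(observed, "sysobs_observed"),
            inherits(params, "sysobs_params"))
  if (!is.finite(obs_precision) || obs_precision <= 0) {
    stop("`obs_precision` must be positive", call. = FALSE)
  }
  params <- apply_free_values(params, free_values)
  u <- approx(driver$time, driver$value, xout = observed$time, rule = 2)$y
  dt <- stats::median(diff(observed$time))
  res <- ekf_loglik_cpp(observed$h_mu, observed$h_M, u, dt, params$a,
                        params$a + params$delta_a, params$b, params$c,
                        params$k, params$k + params$delta_k,
                        params$sigma_mu, params$sigma_M,
                        noise_mode_int(noise), noise$shared_increments,
                        1 / obs_precision)
  structure(res$loglik, repairs = res$repairs)
}

# finite-difference gradient and Hessian (central differences)
fd_grad_hess <- function(fn, x, h) {
  d <- length(x)
  f0 <- fn(x)
  fp <- fm <- numeric(d)
  for (i in seq_len(d)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    fp[i] <- fn(xp)
    fm[i] <- fn(xm)
  }
  g <- (fp - fm) / (2 * h)
  H <- matrix(0, d, d)
  diag(H) <- (fp + fm - 2 * f0) / h^2
  if (d > 1) {
    for (i in 1:(d - 1)) {
      for (j in (i + 1):d) {
        xpp <- x; xpp[i] <- x[i] + h; xpp[j] <- x[j] + h
        xpm <- x; xpm[i] <- x[i] + h; xpm[j] <- x[j] - h
        xmp <- x; xmp[i] <- x[i] - h; xmp[j] <- x[j] + h
        xmm <- x; xmm[i] <- x[i] - h; xmm[j] <- x[j] - h
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h^2)
      }
    }
  }
  list(value = f0, grad = g, hess = H)
}

# negative Hessian -> SPD precision matrix (eigenvalue flooring)
make_spd <- function(M, floor_rel = 1e-8) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  fl <- max(abs(e$values), 1e-12) * floor_rel
  vals <- pmax(e$values, fl)
  list(mat = e$vectors %*% (vals * t(e$vectors)),
       repaired = any(e$values < fl))
}

laplace_f <- function(J, hess) {
  prec <- make_spd(-hess)
  Sigma <- solve(prec$mat)
  Sigma <- (Sigma + t(Sigma)) / 2
  d <- nrow(Sigma)
  list(F = J + 0.5 * (d * log(2 * pi) + ldet(Sigma)), Sigma = Sigma)
}

#' Variational-Laplace fit of a log-joint objective
#'
#' Core optimizer behind [fit_pair()], exposed so any log-likelihood can be
#' inverted under a Gaussian prior (e.g. conjugate linear-Gaussian checks).
#' Performs Gauss-Newton ascent with Levenberg-Marquardt damping on
#' \eqn{J(m) = \log p(y \mid m) + \log p(m)}, with gradients and curvature by
#' central finite differences. The free energy is the Laplace approximation
#' to the log evidence,
#' \deqn{F = J(m) + \tfrac12 \log\det(2\pi\Sigma),}
#' with \eqn{\Sigma} the inverse negative curvature of \eqn{J} at \eqn{m};
#' equivalently accuracy minus complexity with complexity = KL(posterior ||
#' prior). A candidate step is accepted only if it does not decrease F, so F
#' is monotone non-decreasing over accepted iterations.
#'
#' @param objective Function taking a named numeric vector of parameters and
#'   returning the data log likelihood in nats.
#' @param prior A [belief()] over the free parameters.
#' @param settings An [inversion_settings()] object.
#' @return A `sysobs_fit` (which is also a `sysobs_belief`): posterior
#'   `names`, `mean`, `cov`, `free_energy`, plus `complexity`, `accuracy`,
#'   `iterations`, `converged`, `f_trace`.
#' @export
laplace_fit <- function(objective, prior, settings = inversion_settings()) {
  stopifnot(inherits(prior, "sysobs_belief"))
  d <- length(prior$names)
  h <- settings$fd_step
  pr_mean <- unname(prior$mean)
  pr_cov <- prior$cov
  Jfun <- function(v) {
    ll <- objective(stats::setNames(v, prior$names))
    if (!is.finite(ll)) return(-Inf)
    ll + dmvnorm_log(v, pr_mean, pr_cov)
  }
  gh_ok <- function(gh) {
    is.finite(gh$value) && all(is.finite(gh$grad)) && all(is.finite(gh$hess))
  }
  m <- pr_mean
  gh <- fd_grad_hess(Jfun, m, h)
  if (!gh_ok(gh)) {
    stop("objective is not finite around the prior mean", call. = FALSE)
  }
  cur <- laplace_f(gh$value, gh$hess)
  F_cur <- cur$F
  lambda <- settings$damping_init
  f_trace <- F_cur
  small_steps <- 0L
  rejections <- 0L
  converged <- FALSE
  iterations <- 0L
  escalations <- 0L
  for (it in seq_len(settings$max_iterations)) {
    iterations <- it
    M <- make_spd(-gh$hess)$mat
    step <- tryCatch(
      solve(M + lambda * diag(pmax(diag(M), 1e-8), d), gh$grad),
      error = function(e) NULL
    )
    if (is.null(step) || any(!is.finite(step))) {
      lambda <- lambda * 2
      escalations <- escalations + 1L
      if (escalations > 8L) {
        stop("singular curvature: damping escalation limit reached",
             call. = FALSE)
      }
      next
    }
    m_new <- m + as.numeric(step)
    gh_new <- fd_grad_hess(Jfun, m_new, h)
    ok <- gh_ok(gh_new)
    if (ok) {
      cand <- laplace_f(gh_new$value, gh_new$hess)
      ok <- is.finite(cand$F) && cand$F >= F_cur
    }
    if (ok) {
      dF <- cand$F - F_cur
      m <- m_new
      gh <- gh_new
      cur <- cand
      F_cur <- cand$F
      f_trace <- c(f_trace, F_cur)
      lambda <- max(lambda / 2, 1e-12)
      rejections <- 0L
      small_steps <- if (dF < settings$f_tolerance) small_steps + 1L else 0L
      if (small_steps >= 3L) {
        converged <- TRUE
        break
      }
    } else {
      lambda <- lambda * 2
      rejections <- rejections + 1L
      # a run of rejected proposals after an already-small accepted step
      # means no uphill step remains at numerical resolution
      if (rejections >= 8L) {
        last_gain <- if (length(f_trace) >= 2) {
          f_trace[length(f_trace)] - f_trace[length(f_trace) - 1]
        } else {
          Inf
        }
        if (last_gain < 10 * settings$f_tolerance) {
          converged <- TRUE
          break
        }
      }
      if (lambda > 1e12) break
    }
  }
  if (!converged) {
    warning("variational Laplace did not converge within max_iterations; ",
            "returning best-so-far", call. = FALSE)
  }
  complexity <- kl_gauss(m, cur$Sigma, pr_mean, pr_cov)
  out <- belief(prior$names, m, cur$Sigma, free_energy = F_cur)
  out$complexity <- complexity
  out$accuracy <- F_cur + complexity
  out$iterations <- iterations
  out$converged <- converged
  out$f_trace <- f_trace
  class(out) <- c("sysobs_fit", class(out))
  out
}

#' Invert the full generative model on an observed pair
#'
#' Fits the full model by variational Laplace over the free parameters named
#' in `prior` (default: `delta_a` and `delta_k` under standard normal priors,
#' plus one shared log-observation-precision hyperparameter with hyperprior
#' N(2, 4) nats). The likelihood is [pair_loglik()] with the supplied noise
#' mode, so deterministic and stochastic inversions use the same interface.
#'
#' @param observed A `sysobs_observed` pair.
#' @param params A [gen_params()] object holding the fixed parameters
#'   (`a`, `b`, `c`, `k`, volatilities); its `delta_a`/`delta_k` values are
#'   ignored for the free parameters.
#' @param driver The `sysobs_driver` that drove the data.
#' @param noise A [noise_spec()] naming the model family to invert.
#' @param prior Optional `sysobs_belief` prior; default [default_prior()].
#' @param settings An [inversion_settings()] object.
#' @param standardize If `TRUE` (deterministic mode only) the likelihood
#'   compares the z-scored model prediction with the z-scored data, so that
#'   per-channel amplitude and offset carry no information. Intended for
#'   empirical channels that were z-scored during preprocessing, where
#'   absolute amplitude is uninformative by construction and the evidence
#'   for observer effects lives in waveform shape.
#' @return A `sysobs_fit`: the Gaussian posterior with its free energy.
#' @export
#' @examples
#' drv <- scene_driver(c(1.3, 2.6), seed = 2)
#' truth <- gen_params(delta_a = 0.5, obs_noise_sd = 0.05)
#' dat <- observe_latent(simulate_latent(drv, truth), truth, seed = 3)
#' \donttest{
#' fit <- fit_pair(dat, gen_params(), drv)
#' tidy(fit)
#' }
fit_pair <- function(observed, params, driver, noise = noise_spec("none"),
                     prior = NULL, settings = inversion_settings(),
                     standardize = FALSE) {
  stopifnot(inherits(observed, "sysobs_observed"),
            inherits(params, "sysobs_params"))
  if (standardize && noise$mode != "none") {
    stop("`standardize = TRUE` is only defined for the deterministic ",
         "(mode = \"none\") likelihood", call. = FALSE)
  }
  if (is.null(prior)) prior <- default_prior(settings)
  u <- approx(driver$time, driver$value, xout = observed$time, rule = 2)$y
  dt <- stats::median(diff(observed$time))
  mode <- noise_mode_int(noise)
  y_mu <- observed$h_mu
  y_M <- observed$h_M
  if (standardize) {
    y_mu <- zscore(y_mu)
    y_M <- zscore(y_M)
  }
  n <- length(y_mu)
  base_prec <- 1 / params$obs_noise_sd^2
  objective <- function(v) {
    p <- params
    if ("delta_a" %in% names(v)) p$delta_a <- v[["delta_a"]]
    if ("delta_k" %in% names(v)) p$delta_k <- v[["delta_k"]]
    prec <- if ("log_precision" %in% names(v)) {
      exp(min(v[["log_precision"]], 50))
    } else {
      base_prec
    }
    if (standardize) {
      paths <- tryCatch(
        heun_paths_cpp(u, dt, p$a, p$a + p$delta_a, p$b, 0, 0, 0L,
                       numeric(n - 1), numeric(n - 1), 0, 0),
        error = function(e) NULL
      )
      if (is.null(paths)) return(-Inf)
      pm <- p$c * tanh(p$k * paths$x_mu)
      pM <- p$c * tanh((p$k + p$delta_k) * paths$x_M)
      if (stats::sd(pm) < 1e-12 || stats::sd(pM) < 1e-12) return(-Inf)
      r2sum <- sum((zscore(pm) - y_mu)^2) + sum((zscore(pM) - y_M)^2)
      n * log(prec / (2 * pi)) - 0.5 * prec * r2sum
    } else {
      res <- ekf_loglik_cpp(y_mu, y_M, u, dt, p$a, p$a + p$delta_a, p$b,
                            p$c, p$k, p$k + p$delta_k, p$sigma_mu,
                            p$sigma_M, mode, noise$shared_increments,
                            1 / prec)
      res$loglik
    }
  }
  fit <- laplace_fit(objective, prior, settings)
  fit$noise_mode <- noise$mode
  fit$standardized <- standardize
  fit
}

#' @export
tidy.sysobs_belief <- function(x, ...) {
  tibble::tibble(term = x$names,
                 estimate = unname(x$mean),
                 std.error = sqrt(pmax(diag(x$cov), 0)))
}

#' @export
glance.sysobs_fit <- function(x, ...) {
  tibble::tibble(free_energy = x$free_energy,
                 accuracy = x$accuracy,
                 complexity = x$complexity,
                 iterations = x$iterations,
                 converged = x$converged)
}
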