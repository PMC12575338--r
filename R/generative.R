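#' Simulate the latent two-scale dynamics
#'
#' Integrates the coupled micro/macro latent states
#' \deqn{\dot x_\mu = a x_\mu + b\upsilon + s_\mu(x_\mu)\,\xi, \qquad
#'       \dot x_M = (a+\delta a) x_M + b\upsilon + s_M(x_M)\,\xi,}
#' with \eqn{s(x) = \sigma} (additive), \eqn{s(x) = \sigma x}
#' (multiplicative) or zero (deterministic), using the Heun
#' predictor-corrector with fixed step `dt`. For stochastic modes the Heun
#' scheme converges to the Stratonovich solution without a drift correction.
#' Wiener increments are drawn as N(0, dt) per step from a seeded stream and
#' stored with the trajectory so the noise-induced observer terms can be
#' recovered afterwards (see [stratonovich_terms()]).
#'
#' The driver is linearly interpolated onto the simulation grid. Initial
#' conditions are zero; `x0` exists as an override for testing closed-form
#' solutions.
#'
#' @param driver A `sysobs_driver` (see [scene_driver()]).
#' @param params A [gen_params()] object.
#' @param noise A [noise_spec()].
#' @param dt Integration step in seconds; defaults to the driver's sampling
#'   interval.
#' @param x0 Length-2 initial state `(x_mu, x_M)`, default `c(0, 0)`.
#' @return A `sysobs_latent`: tibble with columns `time`, `x_mu`, `x_M`, `u`
#'   (interpolated driver), plus attributes `dt`, `noise` and the realized
#'   Wiener increments `dw` (a list with elements `mu` and `M`; zero-length
#'   when `mode = "none"`).
#' @export
#' @examples
#' drv <- scene_driver(c(2), fs = 250, duration = 4, seed = 1)
#' lat <- simulate_latent(drv, gen_params(), noise_spec("none"))
#' head(lat)
simulate_latent <- function(driver, params, noise = noise_spec("none"),
                            dt = NULL, x0 = c(0, 0)) {
  stopifnot(inherits(driver, "sysobs_driver"),
            inherits(params, "sysobs_params"),
            inherits(noise, "sysobs_noise"))
  if (is.null(dt)) dt <- stats::median(diff(driver$time))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a positive scalar", call. = FALSE)
  }
  t0 <- driver$time[1]
  t_end <- driver$time[nrow(driver)]
  n <- floor((t_end - t0) / dt + 1e-9) + 1
  times <- t0 + dt * (seq_len(n) - 1)
  u <- approx(driver$time, driver$value, xout = times, rule = 2)$y
  mode <- noise_mode_int(noise)
  if (mode > 0) {
    dw <- with_seed(noise$seed, {
      dw_mu <- rnorm(n - 1, sd = sqrt(dt))
      dw_M <- if (noise$shared_increments) dw_mu else rnorm(n - 1, sd = sqrt(dt))
      list(mu = dw_mu, M = dw_M)
    })
  } else {
    dw <- list(mu = numeric(), M = numeric())
  }
  dw_mu_in <- if (mode > 0) dw$mu else numeric(n - 1)
  dw_M_in <- if (mode > 0) dw$M else numeric(n - 1)
  paths <- heun_paths_cpp(u, dt, params$a, params$a + params$delta_a,
                          params$b, params$sigma_mu, params$sigma_M, mode,
                          dw_mu_in, dw_M_in, x0[1], x0[2])
  out <- tibble::tibble(time = times, x_mu = paths$x_mu, x_M = paths$x_M,
                        u = u)
  attr(out, "dt") <- dt
  attr(out, "noise") <- noise
  attr(out, "params") <- params
  attr(out, "dw") <- dw
  class(out) <- c("sysobs_latent", class(out))
  out
}

#' Apply the observer functions to a latent trajectory
#'
#' Maps latent states through the two sigmoidal observers,
#' \eqn{h_\mu = c\tanh(k x_\mu) + \epsilon} and
#' \eqn{h_M = c\tanh((k+\delta k) x_M) + \epsilon'}, where \eqn{\epsilon} and
#' \eqn{\epsilon'} are independent white Gaussian sequences with standard
#' deviation `obs_noise_sd`. Set `obs_noise_sd = 0` in `params` for the
#' noise-free mapping.
#'
#' @param latent A `sysobs_latent` from [simulate_latent()].
#' @param params A [gen_params()] object.
#' @param seed Integer seed for the observation noise.
#' @return A `sysobs_observed`: tibble with columns `time`, `h_mu`, `h_M`,
#'   and an `fs` attribute.
#' @export
observe_latent <- function(latent, params, seed = 1L) {
  stopifnot(inherits(latent, "sysobs_latent"),
            inherits(params, "sysobs_params"))
  stopifnot(all(is.finite(latent$x_mu)), all(is.finite(latent$x_M)))
  h_mu <- params$c * tanh(params$k * latent$x_mu)
  h_M <- params$c * tanh((params$k + params$delta_k) * latent$x_M)
  n <- length(h_mu)
  if (params$obs_noise_sd > 0) {
    eps <- with_seed(seed, matrix(rnorm(2 * n, sd = params$obs_noise_sd),
                                  ncol = 2))
    h_mu <- h_mu + eps[, 1]
    h_M <- h_M + eps[, 2]
  }
  new_observed(latent$time, h_mu, h_M, fs = 1 / attr(latent, "dt"))
}

new_observed <- function(times, h_mu, h_M, fs) {
  stopifnot(all(is.finite(h_mu)), all(is.finite(h_M)))
  out <- tibble::tibble(time = times, h_mu = h_mu, h_M = h_M)
  attr(out, "fs") <- fs
  class(out) <- c("sysobs_observed", class(out))
  out
}

#' Coerce a pair of channel series to an observed pair
#'
#' @param time Time grid (seconds, uniform).
#' @param h_mu,h_M Micro/macro channel values.
#' @return A `sysobs_observed`.
#' @export
as_observed <- function(time, h_mu, h_M) {
  stopifnot(length(time) == length(h_mu), length(h_mu) == length(h_M))
  new_observed(time, h_mu, h_M, fs = 1 / stats::median(diff(time)))
}

#' Stratonovich difference decomposition
#'
#' Decomposes the time derivative of the cross-scale signal difference
#' \eqn{h_\mu - h_M} along a stored stochastic trajectory into
#' \deqn{\underbrace{g_\mu' f_\mu - g_M' f_M}_{\mathrm{degenerate}} +
#'       \underbrace{s_\mu \xi_\mu g_\mu' - s_M \xi_M g_M'}_{\mathrm{observers\ only}},}
#' where \eqn{g' } is the observer slope \eqn{c\,k\,\mathrm{sech}^2(kx)},
#' \eqn{f} the drift, \eqn{s} the diffusion coefficient (\eqn{\sigma} additive,
#' \eqn{\sigma x} multiplicative) and \eqn{\xi} the white-noise realization
#' recovered from the stored Wiener increments as `dw / dt`. The first term
#' confounds system and observer properties; the second depends on the
#' observer sensitivities only, which is what makes state noise informative.
#'
#' Terms are evaluated at the left endpoint of each integration interval
#' (times `1 .. n-1` of the trajectory); their sum reconstructs the interval
#' finite difference of the noise-free observed difference up to integrator
#' truncation error. Without stored increments (deterministic mode) the
#' observer-only term is identically zero.
#'
#' @param latent A `sysobs_latent` carrying stored increments.
#' @param params The [gen_params()] used to generate it.
#' @return A tibble with columns `time`, `degenerate`, `observer_only`.
#' @export
stratonovich_terms <- function(latent, params) {
  stopifnot(inherits(latent, "sysobs_latent"),
            inherits(params, "sysobs_params"))
  n <- nrow(latent)
  dt <- attr(latent, "dt")
  noise <- attr(latent, "noise")
  dw <- attr(latent, "dw")
  if (length(dw$mu) > 0 && length(dw$mu) != n - 1) {
    stop("stored increments do not match the trajectory length",
         call. = FALSE)
  }
  i <- seq_len(n - 1)
  x_mu <- latent$x_mu[i]
  x_M <- latent$x_M[i]
  u <- latent$u[i]
  k_mu <- params$k
  k_M <- params$k + params$delta_k
  gp_mu <- params$c * k_mu * (1 - tanh(k_mu * x_mu)^2)
  gp_M <- params$c * k_M * (1 - tanh(k_M * x_M)^2)
  f_mu <- params$a * x_mu + params$b * u
  f_M <- (params$a + params$delta_a) * x_M + params$b * u
  if (length(dw$mu) == 0) {
    xi_mu <- xi_M <- numeric(n - 1)
    s_mu <- s_M <- numeric(n - 1)
  } else {
    xi_mu <- dw$mu / dt
    xi_M <- dw$M / dt
    if (noise$mode == "multiplicative") {
      s_mu <- params$sigma_mu * x_mu
      s_M <- params$sigma_M * x_M
    } else {
      s_mu <- rep(params$sigma_mu, n - 1)
      s_M <- rep(params$sigma_M, n - 1)
    }
  }
  tibble::tibble(
    time = latent$time[i],
    degenerate = gp_mu * f_mu - gp_M * f_M,
    observer_only = s_mu * xi_mu * gp_mu - s_M * xi_M * gp_M
  )
}
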