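#' Generative model parameters
#'
#' Bundles all scalar parameters of the two-scale generative model. The latent
#' dynamics are linear time-invariant,
#' \deqn{\dot x_\mu = a x_\mu + b \upsilon, \qquad
#'       \dot x_M = (a + \delta a) x_M + b \upsilon,}
#' and each scale is observed through its own sigmoidal observer function,
#' \deqn{h_\mu = c \tanh(k x_\mu), \qquad h_M = c \tanh((k + \delta k) x_M),}
#' with optional additive observation noise on both channels. In stochastic
#' modes the state equations gain Stratonovich noise terms with volatilities
#' `sigma_mu` and `sigma_M` (see [noise_spec()]).
#'
#' `delta_a` captures a deviation in the macroscopic *dynamics* (a system
#' effect); `delta_k` a deviation in the macroscopic *observation* gain (an
#' observer effect). Disentangling the two is the point of the package.
#'
#' @param a Intrinsic dynamical rate (1/s). Negative for stable dynamics; a
#'   warning is issued otherwise.
#' @param b Input gain applied to the exogenous driver (dimensionless).
#' @param c Observer amplitude: the saturation level of the sigmoid
#'   (signal units). Must be positive.
#' @param k Observer input gain (1/state units). Must be positive.
#' @param delta_a Macroscopic dynamics deviation (1/s).
#' @param delta_k Macroscopic observer-gain deviation (1/state units);
#'   `k + delta_k` must remain positive.
#' @param sigma_mu,sigma_M Volatility constants of the micro/macro state noise
#'   (state units per sqrt-second). Non-negative.
#' @param obs_noise_sd Observation noise standard deviation (signal units).
#'   Non-negative.
#' @return An object of class `sysobs_params` (a named list).
#' @seealso [reduce_params()], [noise_spec()], [simulate_latent()]
#' @export
#' @examples
#' gen_params(a = -1, delta_a = 0.5)
gen_params <- function(a = -1, b = 1, c = 1, k = 1,
                       delta_a = 0, delta_k = 0,
                       sigma_mu = 0.2, sigma_M = 0.2,
                       obs_noise_sd = 0.05) {
  p <- list(a = a, b = b, c = c, k = k, delta_a = delta_a, delta_k = delta_k,
            sigma_mu = sigma_mu, sigma_M = sigma_M,
            obs_noise_sd = obs_noise_sd)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]])) {
      stop("parameter `", nm, "` must be a finite scalar", call. = FALSE)
    }
  }
  if (c <= 0) stop("`c` must be positive", call. = FALSE)
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  if (k + delta_k <= 0) stop("`k + delta_k` must be positive", call. = FALSE)
  if (sigma_mu < 0 || sigma_M < 0) {
    stop("volatilities must be non-negative", call. = FALSE)
  }
  if (obs_noise_sd < 0) {
    stop("`obs_noise_sd` must be non-negative", call. = FALSE)
  }
  if (a >= 0 || a + delta_a >= 0) {
    warning("unstable latent dynamics: `a` and `a + delta_a` should be ",
            "negative for a stable simulation", call. = FALSE)
  }
  structure(p, class = "sysobs_params")
}

#' @export
print.sysobs_params <- function(x, ...) {
  cat("<sysobs_params>\n")
  cat(sprintf("  dynamics : a = %g, delta_a = %g, b = %g\n",
              x$a, x$delta_a, x$b))
  cat(sprintf("  observers: c = %g, k = %g, delta_k = %g\n",
              x$c, x$k, x$delta_k))
  cat(sprintf("  noise    : sigma_mu = %g, sigma_M = %g, obs sd = %g\n",
              x$sigma_mu, x$sigma_M, x$obs_noise_sd))
  invisible(x)
}

#' Construct a reduced model
#'
#' The two reduced models of the framework pin one deviation parameter to
#' zero: `"identical_observers"` sets `delta_k = 0` so all cross-scale
#' variation is dynamical; `"identical_systems"` sets `delta_a = 0` so all
#' variation lies in the observation mappings.
#'
#' @param params A [gen_params()] object (the full model).
#' @param which `"identical_observers"` or `"identical_systems"`.
#' @return A `sysobs_params` object with the corresponding deviation zeroed.
#' @export
#' @examples
#' full <- gen_params(delta_a = 0.5, delta_k = 0.3)
#' reduce_params(full, "identical_observers")$delta_k
reduce_params <- function(params,
                          which = c("identical_observers",
                                    "identical_systems")) {
  stopifnot(inherits(params, "sysobs_params"))
  which <- match.arg(which)
  if (which == "identical_observers") params$delta_k <- 0 else params$delta_a <- 0
  params
}

#' Process noise specification
#'
#' @param mode `"none"` (deterministic), `"additive"` (constant volatility) or
#'   `"multiplicative"` (volatility proportional to the state). With
#'   `mode = "none"` all process noise is suppressed regardless of the sigma
#'   values in [gen_params()].
#' @param shared_increments If `TRUE` (default) one Wiener path drives both
#'   scales, so cross-scale differences in the noise response are attributable
#'   to the observers and volatilities alone; if `FALSE` the two scales
#'   receive independent paths.
#' @param seed Integer seed for the Wiener increments.
#' @return An object of class `sysobs_noise`.
#' @export
noise_spec <- function(mode = c("none", "additive", "multiplicative"),
                       shared_increments = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.logical(shared_increments), length(shared_increments) == 1)
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1, !is.na(seed))
  structure(list(mode = mode, shared_increments = shared_increments,
                 seed = seed),
            class = "sysobs_noise")
}

noise_mode_int <- function(noise) {
  match(noise$mode, c("none", "additive", "multiplicative")) - 1L
}

#' @export
print.sysobs_noise <- function(x, ...) {
  cat(sprintf("<sysobs_noise> mode = %s, shared = %s, seed = %d\n",
              x$mode, x$shared_increments, x$seed))
  invisible(x)
}
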