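#' Scene-based exogenous driver
#'
#' Builds the piecewise-constant exogenous input \eqn{\upsilon(t)} that
#' emulates a movie's scene structure: each scene (segment between successive
#' boundaries) is assigned one independent Uniform(0, 1) draw, constant within
#' the scene.
#'
#' @param scene_boundaries Sorted interior scene-cut times in seconds, all
#'   within `(0, duration)`. An empty vector yields a single-scene (constant)
#'   driver.
#' @param fs Sampling rate in Hz.
#' @param duration Total duration in seconds.
#' @param seed Integer seed for the per-scene draws.
#' @param values Optional explicit per-scene values (length = number of
#'   scenes); overrides the random draws. `values = "ordinal"` assigns each
#'   scene its index scaled to `[0, 1]`.
#' @return A `sysobs_driver`: a tibble with columns `time` and `value`,
#'   carrying the scene boundaries and construction parameters as attributes.
#' @seealso [add_fluctuations()], [random_scene_boundaries()]
#' @export
#' @examples
#' drv <- scene_driver(c(1, 2.5), fs = 250, duration = 4, seed = 1)
#' length(unique(drv$value))
scene_driver <- function(scene_boundaries, fs = 250, duration = 4,
                         seed = 1L, values = NULL) {
  stopifnot(fs > 0, duration > 0)
  b <- as.numeric(scene_boundaries)
  if (length(b) > 0) {
    if (is.unsorted(b, strictly = TRUE)) {
      stop("`scene_boundaries` must be strictly increasing", call. = FALSE)
    }
    if (any(b <= 0) || any(b >= duration)) {
      stop("`scene_boundaries` must lie strictly inside (0, duration)",
           call. = FALSE)
    }
  }
  n <- round(fs * duration)
  times <- (seq_len(n) - 1) / fs
  n_scenes <- length(b) + 1L
  if (is.null(values)) {
    vals <- with_seed(seed, runif(n_scenes))
  } else if (identical(values, "ordinal")) {
    vals <- seq_len(n_scenes) / n_scenes
  } else {
    stopifnot(length(values) == n_scenes)
    vals <- as.numeric(values)
  }
  idx <- findInterval(times, b) + 1L
  new_driver(times, vals[idx], scene_boundaries = b,
             meta = list(fs = fs, duration = duration, seed = seed,
                         n_scenes = n_scenes, scene_values = vals))
}

new_driver <- function(times, values, scene_boundaries = numeric(),
                       meta = list()) {
  stopifnot(length(times) == length(values), all(is.finite(values)))
  out <- tibble::tibble(time = times, value = values)
  attr(out, "scene_boundaries") <- scene_boundaries
  attr(out, "meta") <- meta
  class(out) <- c("sysobs_driver", class(out))
  out
}

#' Coerce a data frame to a driver signal
#'
#' @param x A data frame with numeric columns `time` (strictly increasing)
#'   and `value`.
#' @param scene_boundaries Optional scene-cut times in seconds.
#' @return A `sysobs_driver`.
#' @export
as_driver <- function(x, scene_boundaries = numeric()) {
  stopifnot(is.data.frame(x), all(c("time", "value") %in% names(x)))
  if (is.unsorted(x$time, strictly = TRUE)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  new_driver(x$time, x$value, scene_boundaries = scene_boundaries,
             meta = list(source = "as_driver"))
}

#' Add fast fluctuations to a driver
#'
#' Approximates the fine structure of real sensory input by adding white
#' Gaussian noise to the scene signal and then applying light temporal
#' smoothing with a Gaussian kernel (reflective boundary handling). With
#' `noise_sd = 0` and `smooth_width = 0` the driver is returned unchanged.
#'
#' @param driver A `sysobs_driver`.
#' @param noise_sd Standard deviation of the added white noise (driver units).
#' @param smooth_width Standard deviation of the Gaussian smoothing kernel in
#'   seconds (default 50 ms).
#' @param seed Integer seed for the noise draws.
#' @return A `sysobs_driver` with the same grid.
#' @export
add_fluctuations <- function(driver, noise_sd = 0.1, smooth_width = 0.05,
                             seed = 1L) {
  stopifnot(inherits(driver, "sysobs_driver"), noise_sd >= 0,
            smooth_width >= 0)
  v <- driver$value
  if (noise_sd == 0 && smooth_width == 0) return(driver)
  if (noise_sd > 0) {
    v <- v + with_seed(seed, rnorm(length(v), sd = noise_sd))
  }
  fs <- 1 / stats::median(diff(driver$time))
  v <- gaussian_smooth(v, smooth_width * fs)
  meta <- attr(driver, "meta")
  meta$fluctuations <- list(noise_sd = noise_sd, smooth_width = smooth_width,
                            seed = seed)
  new_driver(driver$time, v,
             scene_boundaries = attr(driver, "scene_boundaries"), meta = meta)
}

# Gaussian kernel smoothing with reflective padding; exact on constants.
gaussian_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  r <- max(1L, ceiling(4 * sd_samples))
  kern <- dnorm(seq(-r, r), sd = sd_samples)
  kern <- kern / sum(kern)
  n <- length(x)
  left <- x[seq(min(r, n), 1)]
  right <- x[seq(n, max(1, n - r + 1))]
  if (length(left) < r) left <- c(rep(x[1], r - length(left)), left)
  if (length(right) < r) right <- c(right, rep(x[n], r - length(right)))
  xp <- c(left, x, right)
  sm <- stats::filter(xp, kern, sides = 2)
  as.numeric(sm[(r + 1):(r + n)])
}

#' Random scene boundaries
#'
#' Draws interior scene-cut times for synthetic experiments: `n_scenes`
#' scenes of random lengths over `duration` seconds, with a minimum scene
#' length of two samples at `fs` so every scene contributes a visible plateau.
#'
#' @param n_scenes Number of scenes.
#' @param duration Total duration in seconds.
#' @param seed Integer seed.
#' @param fs Sampling rate used to enforce the minimum scene length.
#' @return Sorted numeric vector of `n_scenes - 1` interior boundaries.
#' @export
random_scene_boundaries <- function(n_scenes = 8, duration = 4, seed = 1L,
                                    fs = 250) {
  stopifnot(n_scenes >= 1)
  if (n_scenes == 1) return(numeric())
  min_gap <- 2 / fs
  with_seed(seed, {
    for (attempt in 1:100) {
      b <- sort(runif(n_scenes - 1, 0, duration))
      gaps <- diff(c(0, b, duration))
      if (all(gaps > min_gap)) return(b)
    }
    stop("could not place scene boundaries with the required spacing",
         call. = FALSE)
  })
}

#' Read a scene-annotation CSV
#'
#' Expects columns `scene_id` and `onset_seconds`; returns interior scene
#' boundaries (onsets after time zero).
#'
#' @param file Path to the CSV.
#' @return Sorted numeric vector of interior boundaries.
#' @export
read_scenes <- function(file) {
  sc <- readr::read_csv(file, col_types = readr::cols(
    scene_id = readr::col_double(),
    onset_seconds = readr::col_double()
  ))
  if (!all(c("scene_id", "onset_seconds") %in% names(sc))) {
    stop("scenes file must have columns scene_id, onset_seconds: ", file,
         call. = FALSE)
  }
  on <- sort(sc$onset_seconds)
  on[on > 0]
}
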