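#' Pin a parameter in a Gaussian belief
#'
#' Produces the reduced prior of Bayesian model reduction by collapsing one
#' parameter: its mean and variance are set to zero and its covariances with
#' the remaining parameters are removed. Pinning `delta_a` yields the
#' "identical systems" reduced model; pinning `delta_k` the "identical
#' observers" one.
#'
#' @param prior A [belief()].
#' @param label Name of the parameter to pin.
#' @return A `sysobs_belief` with the named component degenerate at zero.
#' @export
#' @examples
#' pr <- belief(c("delta_a", "delta_k"), c(0, 0), diag(2))
#' pin_parameter(pr, "delta_a")$cov
pin_parameter <- function(prior, label) {
  stopifnot(inherits(prior, "sysobs_belief"))
  i <- match(label, prior$names)
  if (is.na(i)) {
    stop("unknown parameter label: ", label, call. = FALSE)
  }
  mean <- prior$mean
  cov <- prior$cov
  mean[i] <- 0
  cov[i, ] <- 0
  cov[, i] <- 0
  belief(prior$names, mean, cov, free_energy = prior$free_energy)
}

#' Bayesian model reduction
#'
#' Re-scores a fitted model under a modified (reduced) prior without
#' refitting. For non-degenerate reduced priors the change in log evidence
#' follows the closed-form Gaussian reduction (log ratio of normalizers in
#' canonical form). For zero-variance pins it is the Savage-Dickey density
#' ratio: the log ratio of the posterior to the prior marginal density at the
#' pinned value, with the reduced posterior given by conditioning the full
#' posterior on that value. The evidence of the reduced model is
#' `posterior$free_energy + delta_f`.
#'
#' @param posterior A `sysobs_fit`/`sysobs_belief` with a free energy.
#' @param prior The prior used for the fit.
#' @param reduced_prior The modified prior (see [pin_parameter()]).
#' @return A list with elements `delta_f` (nats) and `reduced_posterior`
#'   (a `sysobs_belief` whose `free_energy` is the reduced model evidence
#'   when the full posterior carried one).
#' @export
model_reduction <- function(posterior, prior, reduced_prior) {
  stopifnot(inherits(posterior, "sysobs_belief"),
            inherits(prior, "sysobs_belief"),
            inherits(reduced_prior, "sysobs_belief"))
  if (!identical(sort(posterior$names), sort(prior$names)) ||
      !identical(sort(posterior$names), sort(reduced_prior$names))) {
    stop("posterior, prior and reduced prior must share parameter labels",
         call. = FALSE)
  }
  ord <- posterior$names
  align <- function(b) {
    i <- match(ord, b$names)
    belief(ord, b$mean[i], b$cov[i, i, drop = FALSE],
           free_energy = b$free_energy)
  }
  prior <- align(prior)
  reduced_prior <- align(reduced_prior)
  vr <- diag(reduced_prior$cov)
  vf <- diag(prior$cov)
  pinned <- which(vr < 1e-12 & vf > 1e-12)
  if (length(pinned) > 0) {
    free <- setdiff(seq_along(ord), pinned)
    if (length(free) > 0) {
      same <- max(abs(reduced_prior$cov[free, free, drop = FALSE] -
                        prior$cov[free, free, drop = FALSE]),
                  abs(reduced_prior$mean[free] - prior$mean[free]))
      if (same > 1e-10) {
        stop("zero-variance reduction requires the unpinned block of the ",
             "reduced prior to match the full prior", call. = FALSE)
      }
    }
    mu_p <- posterior$mean[pinned]
    S_pp <- posterior$cov[pinned, pinned, drop = FALSE]
    log_q <- dmvnorm_log(rep(0, length(pinned)), mu_p, S_pp)
    log_p <- dmvnorm_log(rep(0, length(pinned)), prior$mean[pinned],
                         prior$cov[pinned, pinned, drop = FALSE])
    delta_f <- log_q - log_p
    mean_r <- posterior$mean
    cov_r <- posterior$cov
    mean_r[pinned] <- 0
    if (length(free) > 0) {
      S_fp <- posterior$cov[free, pinned, drop = FALSE]
      gain <- S_fp %*% solve(S_pp)
      mean_r[free] <- posterior$mean[free] +
        as.numeric(gain %*% (0 - mu_p))
      cov_r[free, free] <- posterior$cov[free, free, drop = FALSE] -
        gain %*% t(S_fp)
    }
    cov_r[pinned, ] <- 0
    cov_r[, pinned] <- 0
    cov_r <- (cov_r + t(cov_r)) / 2
  } else {
    # closed-form Gaussian reduction in canonical (precision) form
    A <- solve(posterior$cov)
    B <- solve(prior$cov)
    C <- solve(reduced_prior$cov)
    a <- A %*% posterior$mean
    b <- B %*% prior$mean
    cc <- C %*% reduced_prior$mean
    K <- A - B + C
    evK <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (any(evK <= 0)) {
      stop("reduced prior is incompatible with the posterior ",
           "(non-positive-definite reduced precision)", call. = FALSE)
    }
    k <- a - b + cc
    Kinv <- solve(K)
    delta_f <- 0.5 * (ldet(A) + ldet(C) - ldet(B) - ldet(K)) +
      0.5 * (as.numeric(t(k) %*% Kinv %*% k) -
               as.numeric(t(a) %*% posterior$cov %*% a) -
               as.numeric(t(cc) %*% reduced_prior$cov %*% cc) +
               as.numeric(t(b) %*% prior$cov %*% b))
    mean_r <- as.numeric(Kinv %*% k)
    cov_r <- (Kinv + t(Kinv)) / 2
  }
  f_r <- if (!is.null(posterior$free_energy)) {
    posterior$free_energy + delta_f
  } else {
    NULL
  }
  list(delta_f = delta_f,
       reduced_posterior = belief(ord, mean_r, cov_r, free_energy = f_r))
}

#' Convert model free energies to posterior model probabilities
#'
#' Under a uniform prior over models, the posterior probability of model
#' \eqn{i} is the softmax of the free energies,
#' \eqn{p_i = \exp(F_i - \max F) / \sum_j \exp(F_j - \max F)}. Free energies
#' are reported relative to the minimum (the lower-evidence model sits at
#' zero).
#'
#' @param free_energies Named numeric vector of free energies (nats), one per
#'   model; at least two, all finite.
#' @return A `sysobs_comparison`: a tibble with columns `model`,
#'   `free_energy` (relative, min at 0) and `probability`, carrying `winner`
#'   and `losing_probability` attributes.
#' @export
#' @examples
#' model_probabilities(c(identical_observers = 3, identical_systems = 0))
model_probabilities <- function(free_energies) {
  f <- free_energies
  if (length(f) < 2) stop("need at least two models", call. = FALSE)
  if (any(!is.finite(f))) {
    stop("free energies must be finite", call. = FALSE)
  }
  if (is.null(names(f))) names(f) <- paste0("model", seq_along(f))
  w <- exp(f - max(f))
  p <- w / sum(w)
  out <- tibble::tibble(model = names(f),
                        free_energy = unname(f - min(f)),
                        probability = unname(p))
  attr(out, "winner") <- names(f)[which.max(f)]
  attr(out, "losing_probability") <- 1 - max(p)
  class(out) <- c("sysobs_comparison", class(out))
  out
}

#' @export
print.sysobs_comparison <- function(x, ...) {
  cat("<sysobs_comparison>\n")
  NextMethod()
  cat(sprintf("winner: %s (losing model probability %.3g)\n",
              attr(x, "winner"), attr(x, "losing_probability")))
  invisible(x)
}

#' @export
tidy.sysobs_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Export a comparison as a two-row CSV
#'
#' @param x A `sysobs_comparison`.
#' @param file Output path.
#' @return The input, invisibly.
#' @export
write_comparison_csv <- function(x, file) {
  stopifnot(inherits(x, "sysobs_comparison"))
  readr::write_csv(tibble::tibble(model = x$model,
                                  f_relative = x$free_energy,
                                  probability = x$probability), file)
  invisible(x)
}
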