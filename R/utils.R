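# internal helpers

zscore <- function(x) (x - mean(x)) / stats::sd(x)

# log determinant of a symmetric matrix
ldet <- function(m) {
  as.numeric(determinant(m, logarithm = TRUE)$modulus)
}

# log density of a multivariate normal via Cholesky (small dimensions)
dmvnorm_log <- function(x, mean, cov) {
  ch <- chol(cov)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z * z)
}

# KL[N(m1, S1) || N(m0, S0)], used as the complexity term of the free energy
kl_gauss <- function(m1, S1, m0, S0) {
  d <- length(m1)
  S0i <- solve(S0)
  dm <- m1 - m0
  0.5 * (sum(diag(S0i %*% S1)) + sum(dm * (S0i %*% dm)) - d +
           ldet(S0) - ldet(S1))
}

# evaluate code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic integer stream derivation (multiplicative congruential step
#' modulo 2^31 - 1), used to give independent, reproducible random streams to
#' the Wiener path, the observation noise, the driver plateau values, and so
#' on, from one master seed.
#'
#' @param seed Master integer seed.
#' @param stream Integer stream index (0, 1, 2, ...).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 0)
#' derive_seed(1, 1)
derive_seed <- function(seed, stream = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + 1009 * (as.numeric(stream) + 1)
  out <- as.integer(s %% m)
  if (out <= 0L) out <- out + 2147483646L
  out
}
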