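# Truncated-normal primitives used by the cohort generator.
# Inverse-CDF sampling keeps draws reproducible under a single RNG stream.

#' Truncated normal distribution helpers
#'
#' \code{rtnorm} draws from a normal distribution truncated to
#' \code{[lower, upper]} by inverse-CDF sampling; \code{tnorm_mean} returns
#' the exact mean of that truncated distribution;
#' \code{calibrate_tnorm_mu} solves for the parent mean \code{mu} such that
#' the truncated mean equals a target (used to calibrate the lesion-diameter
#' distribution to the printed cohort mean on a hard range).
#'
#' @param n Number of draws.
#' @param mu,sigma Parent normal mean and SD (\code{sigma > 0}).
#' @param lower,upper Truncation bounds, \code{lower < upper}.
#' @param target Desired truncated mean (must lie strictly inside the bounds).
#' @return \code{rtnorm}: numeric vector in \code{[lower, upper]};
#'   \code{tnorm_mean}, \code{calibrate_tnorm_mu}: scalar.
#' @keywords internal
#' @export
rtnorm <- function(n, mu, sigma, lower = -Inf, upper = Inf) {
  stopifnot(sigma > 0, lower < upper)
  plo <- pnorm(lower, mu, sigma)
  phi <- pnorm(upper, mu, sigma)
  if (phi - plo <= 0)
    stop("truncation interval has no probability mass under the parent")
  qnorm(runif(n, plo, phi), mu, sigma)
}

#' @rdname rtnorm
#' @export
tnorm_mean <- function(mu, sigma, lower = -Inf, upper = Inf) {
  stopifnot(sigma > 0, lower < upper)
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  mu + sigma * (dnorm(a) - dnorm(b)) / z
}

#' @rdname rtnorm
#' @export
calibrate_tnorm_mu <- function(target, sigma, lower, upper) {
  stopifnot(target > lower, target < upper)
  # +/- 3 sigma keeps both truncation z-scores in pnorm's working range
  uniroot(function(mu) tnorm_mean(mu, sigma, lower, upper) - target,
          interval = c(lower - 3 * sigma, upper + 3 * sigma),
          tol = 1e-10)$root
}

# Symmetric positive truncation about the mean: preserves the printed mean
# exactly while keeping every draw strictly positive.
t1_trunc_bounds <- function(mean, sd, k_max = 3) {
  k <- min(k_max, 0.99 * mean / sd)
  c(mean - k * sd, mean + k * sd)
}
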