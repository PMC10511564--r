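#' Derive a named sub-seed from a global seed
#'
#' One global seed is fanned out to the package's independent random stages
#' (cohort sampling, per-lesion noise, Monte-Carlo estimation) through a
#' deterministic, documented scheme: the stage name is hashed by a small
#' polynomial rolling hash and folded into the global seed modulo
#' \eqn{2^{31} - 1}.  This keeps stages re-runnable in isolation without
#' coupling their streams.
#'
#' @param seed Integer global seed.
#' @param name Character stage name, e.g. \code{"cohort"} or
#'   \code{"lesion-12"}.
#' @return A single integer in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name),
            length(name) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 131 + cc) %% m
  as.integer((abs(as.numeric(seed)) %% m + h) %% (m - 1) + 1)
}
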