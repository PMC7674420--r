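#' Derive a child seed from a master seed and an index path
#'
#' All randomness in the package flows from one master seed; stage- and
#' iteration-level seeds are derived deterministically from it with a small
#' multiplicative hash, so any component can be rerun in isolation and
#' reproduce the full pipeline's draws. The result stays below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param ... integer indices identifying the consumer (stage, shuffle, fold...).
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, ...) {
  ix <- c(seed, ...)
  s <- 0
  for (v in ix) s <- (s * 48271 + as.double(v) + 1) %% 2147483647
  as.integer(s %% 2147483645) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample from a one-sided truncated normal via inverse-CDF
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal.
#' @param upper if `TRUE`, truncate above at `at` (support `(-Inf, at)`),
#'   otherwise truncate below (support `[at, Inf)`).
#' @param at truncation point.
#' @return numeric vector of length `n`.
#' @keywords internal
rtruncnorm1 <- function(n, mean, sd, upper = TRUE, at = 0) {
  a <- pnorm(at, mean, sd)
  u <- if (upper) runif(n, 0, a) else runif(n, a, 1)
  qnorm(u, mean, sd)
}

# mean of N(mean, sd) truncated above (upper=TRUE) or below at `at`
truncnorm_mean <- function(mean, sd, upper = TRUE, at = 0) {
  alpha <- (at - mean) / sd
  if (upper) mean - sd * dnorm(alpha) / pnorm(alpha)
  else mean + sd * dnorm(alpha) / (1 - pnorm(alpha))
}

#' @importFrom stats dnorm
# location mu such that N(mu, sd) truncated at 0 has the target mean;
# target < 0 pairs with upper truncation, target >= 0 with lower.
calibrate_truncnorm_location <- function(target_mean, sd) {
  upper <- target_mean < 0
  f <- function(mu) truncnorm_mean(mu, sd, upper = upper) - target_mean
  uniroot(f, interval = c(target_mean - 6 * sd, target_mean + 6 * sd),
          tol = 1e-10)$root
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
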