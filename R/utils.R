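# Small numerical helpers shared across the package.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return \code{log(sum(exp(x)))} computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Stable log-mean-exp
#' @keywords internal
logmeanexp <- function(x) logsumexp(x) - log(length(x))

#' Truncated-normal random draws via inverse CDF
#'
#' Draws from a normal(mean, sd) restricted to (lower, upper). The parent
#' parameters are those of the untruncated normal; bounds here are always
#' within a few SD of the mean, where the inverse-CDF method is accurate.
#'
#' @param n number of draws.
#' @param mean,sd parent normal parameters (sd > 0).
#' @param lower,upper truncation bounds.
#' @return numeric vector of length \code{n}.
#' @keywords internal
rtnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

#' Truncated-normal density
#' @param log return log density?
#' @keywords internal
dtnorm <- function(x, mean, sd, lower, upper, log = FALSE) {
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  ld <- stats::dnorm(x, mean, sd, log = TRUE) - log(z)
  ld[x < lower | x > upper] <- -Inf
  if (log) ld else exp(ld)
}

#' Inverse-gamma random draws
#'
#' X ~ IG(shape, scale) iff 1/X ~ Gamma(shape, rate = scale); the IG mean is
#' scale / (shape - 1) for shape > 1.
#' @keywords internal
rinvgamma <- function(n, shape, scale) 1 / stats::rgamma(n, shape = shape, rate = scale)

#' Inverse-gamma log density
#' @keywords internal
dinvgamma_log <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

logit <- function(p) log(p) - log1p(-p)
plogis_ <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Counter-based seed derivation: one global seed fans out to per-stage seeds
# so stages are independently reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 1000003 + stage * 7919) %% 2147483647
}
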