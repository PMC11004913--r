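# Deterministic hyperparameters of the hierarchical change-point model.
#
# Per marker k (on the log(Z+4) scale):
#   theta_ik ~ N(mu_theta_k, sig2_theta_k)      subject baseline
#   mu_theta_k ~ N(mu0_k, sig20_k)              population baseline mean
#   sig2_theta_k ~ IG(a_theta_k, b_theta_k)     between-subject variance
#   log gamma_ik ~ N(mu_gamma_k, sig2_gamma_k)  post-change slope (log scale)
#   mu_gamma_k ~ N(mu1_k, sig21_k)
#   sig2_gamma_k ~ IG(a_gamma_k, b_gamma_k)
#   sig2_k ~ IG(a, b)                           residual variance
#   tau_ik ~ TN_(d_i - tau_star, d_i)(d_i - mu_tau, sig2_tau)
# Shared across markers:
#   plogis(mu_I) ~ Beta(p1, p2)  (mean 0.85, sd 0.05 by default: ~15% of
#     cases never show a marker increment)
#   eta_I ~ Beta(p3, p4)

#' Match Beta parameters to a mean and standard deviation
#'
#' @param mean target mean in (0, 1).
#' @param sd target standard deviation; must satisfy sd^2 < mean (1 - mean).
#' @return named numeric vector \code{c(p1, p2)} (shape1, shape2).
#' @examples
#' match_beta_moments(0.85, 0.05) # c(42.5, 7.5)
#' @export
match_beta_moments <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("'mean' must lie in (0, 1)")
  if (sd <= 0 || sd^2 >= mean * (1 - mean)) {
    stop("infeasible Beta moments: need sd^2 < mean (1 - mean)")
  }
  s <- mean * (1 - mean) / sd^2 - 1
  c(p1 = mean * s, p2 = (1 - mean) * s)
}

#' Hyperparameters for the Bayesian change-point model
#'
#' Returns the full set of deterministic hyperparameters. Marker-level
#' entries are length-\code{K} vectors (recycled if scalars are given).
#' Defaults describe CA125, HE4 and glycodelin on the log(Z+4) scale:
#' population medians of roughly 12 U/mL, 50 pmol/L and 30 ng/mL give
#' baseline means near 2.8, 4.0 and 3.5 log units; residual fluctuation
#' around 0.3 and between-subject spread around 0.4 log units.
#'
#' @param K number of markers.
#' @param mu0,sig20 mean and variance of the population-baseline prior.
#' @param a_theta,b_theta inverse-gamma shape/scale of the between-subject
#'   variance prior.
#' @param mu1,sig21 mean and variance of the population slope prior (slopes
#'   live on the log scale; \code{mu1 = 0} centres gamma at 1 log-unit/year).
#' @param a_gamma,b_gamma inverse-gamma prior of the slope variance.
#' @param a,b inverse-gamma prior of the residual variance.
#' @param indicator_mean,indicator_sd prior mean and sd of the logistic
#'   transform of \code{mu_I}; the default (0.85, 0.05) encodes that about
#'   15\% of cases never show an increment in a marker.
#' @param p3,p4 Beta prior of the coupling coefficient \code{eta_I}.
#' @param mu_tau mean change-point lead before last measurement, years.
#' @param sig2_tau variance of the change-point location, years^2.
#' @param tau_star assumed preclinical duration, years; change points are
#'   truncated to \code{(d_i - tau_star, d_i)}.
#' @param R coupling matrix; defaults to strictly upper triangular ones.
#' @return object of class \code{bcp_hyperparams} (a named list).
#' @export
bcp_hyperparams <- function(K = 3,
                            mu0 = c(2.8, 4.0, 3.5)[seq_len(K)],
                            sig20 = 0.25,
                            a_theta = 3, b_theta = 0.32,
                            mu1 = 0, sig21 = 0.25,
                            a_gamma = 3, b_gamma = 0.5,
                            a = 3, b = 0.18,
                            indicator_mean = 0.85, indicator_sd = 0.05,
                            p3 = 1, p4 = 1,
                            mu_tau = 2, sig2_tau = 0.75, tau_star = 5,
                            R = default_coupling_matrix(K)) {
  if (length(mu0) != K) mu0 <- rep_len(mu0, K)
  p12 <- match_beta_moments(indicator_mean, indicator_sd)
  h <- list(
    K = K,
    mu0 = mu0, sig20 = rep_len(sig20, K),
    a_theta = rep_len(a_theta, K), b_theta = rep_len(b_theta, K),
    mu1 = rep_len(mu1, K), sig21 = rep_len(sig21, K),
    a_gamma = rep_len(a_gamma, K), b_gamma = rep_len(b_gamma, K),
    a = rep_len(a, K), b = rep_len(b, K),
    p1 = unname(p12[1]), p2 = unname(p12[2]),
    p3 = p3, p4 = p4,
    mu_tau = mu_tau, sig2_tau = sig2_tau, tau_star = tau_star,
    R = R
  )
  stopifnot(all(h$sig20 > 0), all(h$a_theta > 0), all(h$b_theta > 0),
            all(h$sig21 > 0), all(h$a_gamma > 0), all(h$b_gamma > 0),
            all(h$a > 0), all(h$b > 0), h$p3 > 0, h$p4 > 0,
            h$sig2_tau > 0, h$tau_star > 0)
  check_coupling_matrix(R, K)
  class(h) <- "bcp_hyperparams"
  h
}

#' @export
print.bcp_hyperparams <- function(x, ...) {
  cat("Change-point model hyperparameters (K =", x$K, "markers)\n")
  cat("  baseline prior:    mu0 =", paste(signif(x$mu0, 3), collapse = ", "),
      " sig20 =", paste(signif(x$sig20, 3), collapse = ", "), "\n")
  cat("  indicator prior:   plogis(mu_I) ~ Beta(", signif(x$p1, 4), ",",
      signif(x$p2, 4), ")\n")
  cat("  coupling prior:    eta_I ~ Beta(", x$p3, ",", x$p4, ")\n")
  cat("  change point:      TN(d - tau*, d), mean d -", x$mu_tau,
      "y, var", x$sig2_tau, "y^2, tau* =", x$tau_star, "y\n")
  invisible(x)
}
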