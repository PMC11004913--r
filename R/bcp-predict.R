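# Posterior-predictive screening.  A new patient's series is scored by the
# ratio of its predictive densities under the case and control models,
# combined with a population prevalence prior (Bayes' rule):
#   P(o=1 | Y) = P(Y | o=1) P(o=1) / sum_o P(Y | o) P(o).
# Subject-level parameters of the new patient are marginalized: the baseline
# theta analytically (compound-symmetric Gaussian), the indicator/slope/
# change-point by fresh draws from their population-level posteriors for
# each retained MCMC draw.

# log N(resid; 0, sig2 I + sig2_th 11') for a matrix of residual rows
# (draws x j), vectorized over draws with per-draw variances.
cs_mvn_logdens <- function(resid, sig2, sig2_th) {
  j <- ncol(resid)
  s <- rowSums(resid); ss <- rowSums(resid^2)
  logdet <- (j - 1) * log(sig2) + log(sig2 + j * sig2_th)
  quad <- (ss - sig2_th / (sig2 + j * sig2_th) * s^2) / sig2
  -0.5 * (j * log(2 * pi) + logdet + quad)
}

# Evenly thinned row indices of the pooled draw matrix.
thin_idx <- function(n_total, n_draws) {
  n_draws <- min(n_draws, n_total)
  unique(round(seq(1, n_total, length.out = n_draws)))
}

#' Posterior-predictive log-density of a biomarker series
#'
#' Monte-Carlo average, over retained posterior draws of the population
#' parameters, of the density of a new patient's multimarker series under
#' the control hypothesis (\code{o = 0}: flat subject baseline) or the case
#' hypothesis (\code{o = 1}: indicator vector drawn from the MRF, slope and
#' change point from their population distributions). The subject baseline
#' is integrated out analytically. Averaging is done on the log scale with
#' log-sum-exp.
#'
#' @param fit a \code{bcp_fit}.
#' @param Y numeric matrix (visits x markers) of transformed levels, marker
#'   columns in \code{fit$markers} order.
#' @param t visit ages in years (length \code{nrow(Y)}).
#' @param o hypothesis, 0 or 1.
#' @param n_draws number of thinned posterior draws to average over.
#' @param seed seed for the per-draw latent sampling.
#' @return scalar log predictive density.
#' @export
posterior_predictive_logdensity <- function(fit, Y, t, o, n_draws = 400,
                                            seed = 1L) {
  stopifnot(inherits(fit, "bcp_fit"), o %in% c(0, 1))
  Y <- as.matrix(Y)
  if (nrow(Y) != length(t)) stop("Y and t disagree on the number of visits")
  draws <- pooled_draws(fit)
  if (nrow(draws) == 0) stop("fit contains no retained samples")
  draws <- draws[thin_idx(nrow(draws), n_draws), , drop = FALSE]
  pp_logdens_draws(draws, fit$hyper, fit$markers, Y, t, o, seed)
}

# Core of the predictive density; `draws` is a pooled population-parameter
# matrix with the bcp_fit column naming.
pp_logdens_draws <- function(draws, hyper, markers, Y, t, o, seed = 1L) {
  set.seed(seed)
  S <- nrow(draws); K <- length(markers); j <- length(t)
  d <- max(t)
  if (o == 1) {
    # one indicator vector per draw, from the MRF at that draw's (mu_I, eta_I)
    states <- mrf_states(K)
    lw <- outer(draws[, "mu_I"], rowSums(states)) +
      outer(draws[, "eta_I"], rowSums((states %*% hyper$R) * states))
    pr <- exp(lw - apply(lw, 1, logsumexp))
    u <- stats::runif(S)
    cum <- t(apply(pr, 1, cumsum))
    Imat <- states[rowSums(cum < u) + 1, , drop = FALSE]
  }
  ld <- numeric(S)
  for (k in seq_len(K)) {
    mth <- draws[, paste0("mu_theta.", markers[k])]
    s2th <- draws[, paste0("sig2_theta.", markers[k])]
    s2 <- draws[, paste0("sig2.", markers[k])]
    resid <- matrix(Y[, k], S, j, byrow = TRUE) - mth
    if (o == 1) {
      act <- Imat[, k] == 1
      if (any(act)) {
        mg <- draws[act, paste0("mu_gamma.", markers[k])]
        s2g <- draws[act, paste0("sig2_gamma.", markers[k])]
        gam <- exp(stats::rnorm(sum(act), mg, sqrt(s2g)))
        tau <- rtnorm(sum(act), d - hyper$mu_tau, sqrt(hyper$sig2_tau),
                      d - hyper$tau_star, d)
        hinge <- pmax(outer(rep(1, sum(act)), t) - tau, 0)
        resid[act, ] <- resid[act, , drop = FALSE] - gam * hinge
      }
    }
    ld <- ld + cs_mvn_logdens(resid, s2, s2th)
  }
  logmeanexp(ld)
}

#' Combine predictive densities with a prevalence prior
#'
#' @param logdens1,logdens0 log predictive densities under case / control.
#' @param prevalence prior disease probability in (0, 1).
#' @return posterior probability of disease.
#' @export
risk_from_logdens <- function(logdens1, logdens0, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  1 / (1 + exp(logdens0 + log1p(-prevalence) - logdens1 - log(prevalence)))
}

# Resolve a prevalence spec (scalar, lookup table with columns age_lower /
# rate, or function of age) at a given age.
prevalence_at <- function(prevalence, age) {
  if (is.function(prevalence)) return(prevalence(age))
  if (is.data.frame(prevalence)) {
    stopifnot(all(c("age_lower", "rate") %in% names(prevalence)))
    tab <- prevalence[order(prevalence$age_lower), ]
    i <- findInterval(age, tab$age_lower)
    if (i < 1) i <- 1
    return(tab$rate[i])
  }
  prevalence
}

#' Posterior risk trajectories from a fitted change-point model
#'
#' For every patient in \code{newdata} and every visit prefix with at least
#' \code{min_visits} visits, computes the posterior probability of disease
#' from the two posterior-predictive densities and the prevalence prior.
#'
#' @param object a \code{bcp_fit}.
#' @param newdata a \code{screening_cohort} carrying the fitted markers.
#' @param prevalence scalar prior prevalence, a lookup table
#'   (\code{data.frame(age_lower, rate)} keyed by age-band lower bounds), or
#'   a function of age. Must be supplied: no population incidence values are
#'   built in.
#' @param min_visits shortest prefix scored (default 2: predictions start
#'   from the second visit).
#' @param n_draws posterior draws averaged per density.
#' @param seed seed for the predictive Monte-Carlo.
#' @param ... unused.
#' @return data.frame: patient_id, visit_index, age_years, risk, model.
#' @export
predict.bcp_fit <- function(object, newdata, prevalence, min_visits = 2,
                            n_draws = 400, seed = 1L, ...) {
  stopifnot(inherits(newdata, "screening_cohort"))
  arr <- cohort_arrays(newdata, object$markers)
  draws <- pooled_draws(object)
  draws <- draws[thin_idx(nrow(draws), n_draws), , drop = FALSE]
  out <- list()
  for (i in seq_len(arr$N)) {
    Ti <- arr$Ti[i]
    if (Ti < min_visits) {
      warning("patient ", arr$ids[i], " has fewer than ", min_visits,
              " visits; skipped")
      next
    }
    for (jj in seq(min_visits, Ti)) {
      tt <- arr$t[i, seq_len(jj)]
      Yp <- matrix(arr$Y[i, seq_len(jj), ], jj, arr$K)
      sd_seed <- derive_seed(seed, i * 1000 + jj)
      l0 <- pp_logdens_draws(draws, object$hyper, object$markers,
                             Yp, tt, 0, sd_seed)
      l1 <- pp_logdens_draws(draws, object$hyper, object$markers,
                             Yp, tt, 1, sd_seed)
      p <- prevalence_at(prevalence, max(tt))
      out[[length(out) + 1]] <- data.frame(
        patient_id = arr$ids[i], visit_index = jj,
        age_years = max(tt),
        risk = risk_from_logdens(l1, l0, p),
        model = "bcp", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
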