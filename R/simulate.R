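# Synthetic-cohort generator.  Emulates the nested case-control screening
# design: annual serum samples, three positively coupled markers, controls
# fluctuating about subject-specific constant baselines, cases with a latent
# change point in the last years before the final screen followed by a
# positive log-scale slope.  The generative model is exactly the hierarchy
# the change-point sampler targets, so latent truth is recorded for
# parameter-recovery tests.

#' Calibrate the MRF sparsity parameter to a marginal indicator frequency
#'
#' Solves for \code{mu_I} such that the per-marker marginal
#' \eqn{P(I_k = 1)} under the coupled MRF equals \code{target}. With
#' \code{eta_I = 0} this is exactly \code{qlogis(target)}.
#'
#' @param target desired marginal change-point probability.
#' @param eta_I coupling coefficient.
#' @param R coupling matrix.
#' @param K number of markers.
#' @export
calibrate_mu_I <- function(target, eta_I, R, K) {
  if (eta_I == 0) return(logit(target))
  marg <- function(mu) {
    pmf <- mrf_pmf(mu, eta_I, R, K)
    mean(colSums(pmf$states * pmf$prob))
  }
  stats::uniroot(function(mu) marg(mu) - target,
                 lower = -20, upper = 20, tol = 1e-10)$root
}

#' Configuration for the synthetic-cohort generator
#'
#' Defaults mirror the study cohort shape: 180 controls / 44 cases; cases
#' carry 2, 3 or 5 annual samples in proportion 10:10:24, controls 4 or 5 in
#' proportion 2:178; three markers (CA125, HE4, glycodelin) on the log(Z+4)
#' scale. About 85\% of case-marker series exhibit a change point, with
#' positive coupling across a patient's markers.
#'
#' @param n_controls,n_cases cohort sizes.
#' @param markers marker names (length K).
#' @param mu_theta,sig2_theta population baseline mean (length K) and
#'   between-subject variance of the log-scale baselines.
#' @param mu_gamma,sig2_gamma mean and variance of log slopes (log-units/yr).
#' @param sig2 residual variance on the log scale.
#' @param indicator_marginal target marginal probability that a case-marker
#'   series has a change point (default 0.85).
#' @param eta_I coupling coefficient of the indicator MRF.
#' @param R coupling matrix (default strictly upper triangular ones).
#' @param mu_tau,sig2_tau,tau_star change-point location prior: truncated
#'   normal on (d - tau_star, d) with parent mean d - mu_tau (years).
#' @param case_visits,case_visit_prob distribution of case visit counts.
#' @param control_visits,control_visit_prob same for controls.
#' @param visit_gap inter-visit gap in years (annual screens).
#' @param entry_age_range uniform range of first-visit ages, years.
#' @param diagnosis_gap years from last screen to clinical diagnosis.
#' @param seed integer seed; a fixed seed reproduces the cohort exactly.
#' @return object of class \code{cohort_generator_config}.
#' @export
cohort_generator_config <- function(n_controls = 180, n_cases = 44,
                                    markers = c("CA125", "HE4", "glycodelin"),
                                    mu_theta = c(2.8, 4.0, 3.5),
                                    sig2_theta = 0.16,
                                    mu_gamma = 0, sig2_gamma = 0.25,
                                    sig2 = 0.09,
                                    indicator_marginal = 0.85,
                                    eta_I = 0.5,
                                    R = default_coupling_matrix(length(markers)),
                                    mu_tau = 2, sig2_tau = 0.75, tau_star = 5,
                                    case_visits = c(2, 3, 5),
                                    case_visit_prob = c(10, 10, 24) / 44,
                                    control_visits = c(4, 5),
                                    control_visit_prob = c(2, 178) / 180,
                                    visit_gap = 1,
                                    entry_age_range = c(50, 73),
                                    diagnosis_gap = 0,
                                    seed = 1L) {
  K <- length(markers)
  cfg <- list(
    n_controls = n_controls, n_cases = n_cases, markers = markers,
    mu_theta = rep_len(mu_theta, K), sig2_theta = rep_len(sig2_theta, K),
    mu_gamma = rep_len(mu_gamma, K), sig2_gamma = rep_len(sig2_gamma, K),
    sig2 = rep_len(sig2, K),
    indicator_marginal = indicator_marginal, eta_I = eta_I, R = R,
    mu_I = calibrate_mu_I(indicator_marginal, eta_I, R, K),
    mu_tau = mu_tau, sig2_tau = sig2_tau, tau_star = tau_star,
    case_visits = case_visits, case_visit_prob = case_visit_prob,
    control_visits = control_visits, control_visit_prob = control_visit_prob,
    visit_gap = visit_gap, entry_age_range = entry_age_range,
    diagnosis_gap = diagnosis_gap, seed = as.integer(seed)
  )
  stopifnot(all(cfg$sig2_theta > 0), all(cfg$sig2_gamma > 0),
            all(cfg$sig2 > 0), cfg$sig2_tau > 0, cfg$tau_star > 0,
            cfg$eta_I >= 0, n_controls >= 0, n_cases >= 0,
            abs(sum(case_visit_prob) - 1) < 1e-8,
            abs(sum(control_visit_prob) - 1) < 1e-8)
  check_coupling_matrix(R, K)
  class(cfg) <- "cohort_generator_config"
  cfg
}

#' Generate a synthetic screening cohort
#'
#' Draws subject-level latents from the generator configuration and emits
#' raw marker levels via the inverse transform \code{exp(Y) - 4}. Controls:
#' \eqn{Y = \theta_{ik} + \epsilon}; cases with an active indicator additionally
#' gain a hinge term \eqn{\gamma_{ik} (t - \tau_{ik})_+}.
#'
#' @param config a \code{cohort_generator_config}.
#' @return a \code{screening_cohort}; element \code{truth} holds the latent
#'   per-patient-and-marker parameters (theta, indicator, gamma, tau) and
#'   attribute \code{"config"} the generating configuration.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_generator_config"))
  set.seed(config$seed)
  K <- length(config$markers)
  N <- config$n_controls + config$n_cases
  status <- rep(c(0, 1), c(config$n_controls, config$n_cases))
  ids <- sprintf("P%04d", seq_len(N))

  rows <- vector("list", N)
  truth <- vector("list", N)
  for (i in seq_len(N)) {
    nv <- if (status[i] == 1) {
      config$case_visits[sample.int(length(config$case_visits), 1,
                                    prob = config$case_visit_prob)]
    } else {
      config$control_visits[sample.int(length(config$control_visits), 1,
                                       prob = config$control_visit_prob)]
    }
    entry <- stats::runif(1, config$entry_age_range[1], config$entry_age_range[2])
    ages <- entry + config$visit_gap * (seq_len(nv) - 1)
    d <- max(ages)
    theta <- stats::rnorm(K, config$mu_theta, sqrt(config$sig2_theta))
    if (status[i] == 1) {
      I <- drop(sample_indicators(1, config$mu_I, config$eta_I, config$R, K))
      gam <- ifelse(I == 1,
                    exp(stats::rnorm(K, config$mu_gamma, sqrt(config$sig2_gamma))),
                    NA_real_)
      tau <- ifelse(I == 1,
                    rtnorm(K, d - config$mu_tau, sqrt(config$sig2_tau),
                           d - config$tau_star, d),
                    NA_real_)
    } else {
      I <- rep(NA_real_, K); gam <- rep(NA_real_, K); tau <- rep(NA_real_, K)
    }
    Y <- matrix(stats::rnorm(nv * K, 0, sqrt(rep(config$sig2, each = nv))), nv, K)
    for (k in seq_len(K)) {
      mu <- theta[k]
      if (status[i] == 1 && !is.na(I[k]) && I[k] == 1) {
        mu <- mu + gam[k] * pmax(ages - tau[k], 0)
      }
      Y[, k] <- Y[, k] + mu
    }
    raw <- exp(Y) - 4
    if (any(raw <= -3.99)) {
      warning("raw level at or below -3.99 clipped for patient ", ids[i])
      raw[raw <= -3.99] <- -3.99 + 1e-6
    }
    rows[[i]] <- data.frame(
      patient_id = ids[i], status = status[i],
      visit_index = rep(seq_len(nv), K),
      age_years = rep(ages, K),
      marker = rep(config$markers, each = nv),
      raw_level = as.vector(raw), stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      patient_id = ids[i], marker = config$markers,
      theta = theta, indicator = I, gamma = gam, tau = tau,
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  case_ids <- ids[status == 1]
  da <- NULL
  if (length(case_ids)) {
    d_case <- vapply(rows[status == 1],
                     function(r) max(r$age_years), numeric(1))
    da <- stats::setNames(d_case + config$diagnosis_gap, case_ids)
  }
  cohort <- as_cohort(long, diagnosis_age = da, markers = config$markers)
  cohort$truth <- do.call(rbind, truth)
  rownames(cohort$truth) <- NULL
  attr(cohort, "config") <- config
  cohort
}

#' Convenience wrapper around the generator
#'
#' @param n_controls,n_cases cohort sizes.
#' @param seed integer seed.
#' @param ... passed to [cohort_generator_config()].
#' @export
simulate_cohort <- function(n_controls = 180, n_cases = 44, seed = 1L, ...) {
  generate_cohort(cohort_generator_config(n_controls = n_controls,
                                          n_cases = n_cases, seed = seed, ...))
}

#' Write the latent truth table of a generated cohort
#' @param cohort a generated \code{screening_cohort} with a \code{truth} table.
#' @param path file path.
#' @export
write_truth_csv <- function(cohort, path) {
  if (is.null(cohort$truth)) stop("cohort carries no truth table")
  utils::write.csv(cohort$truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
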