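# MCMC driver for the joint change-point model and the fitted-model class.

#' MCMC control settings for the change-point sampler
#'
#' Defaults are the full-scale run: two chains of 40,000 iterations with a
#' 5,000-iteration burn-in, retaining 2 x 35,000 = 70,000 draws.
#'
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations per chain.
#' @param n_chains number of independent chains.
#' @param adapt_mh adapt the coupling-step random-walk scales during burn-in
#'   only (frozen afterwards, preserving the stationary distribution).
#' @export
bcp_control <- function(n_iter = 40000, burn_in = 5000, n_chains = 2,
                        adapt_mh = TRUE) {
  stopifnot(n_iter > burn_in, burn_in >= 0, n_chains >= 1)
  structure(list(n_iter = n_iter, burn_in = burn_in, n_chains = n_chains,
                 adapt_mh = adapt_mh), class = "bcp_control")
}

#' Retained posterior sample count implied by a control object
#' @param control a \code{bcp_control}.
#' @export
retained_samples <- function(control) {
  control$n_chains * (control$n_iter - control$burn_in)
}

pop_par_names <- function(markers) {
  c(paste0("mu_theta.", markers), paste0("sig2_theta.", markers),
    paste0("mu_gamma.", markers), paste0("sig2_gamma.", markers),
    paste0("sig2.", markers), "mu_I", "eta_I")
}

# One chain.  `updates` switches individual blocks on/off (used by the
# stationarity and prior-limit tests); `init` optionally supplies the
# starting state instead of a prior draw.
run_bcp_chain <- function(arr, hyper, control, seed, init = NULL,
                          updates = list()) {
  up <- utils::modifyList(list(theta = TRUE, gamma_tau = TRUE, rj = TRUE,
                               population = TRUE, coupling = TRUE), updates)
  set.seed(seed)
  state <- init %||% draw_state_from_prior(arr, hyper)
  kept <- control$n_iter - control$burn_in
  K <- arr$K
  pop <- matrix(NA_real_, kept, 5 * K + 2,
                dimnames = list(NULL, pop_par_names(arr$markers)))
  I_sum <- matrix(0, arr$N, K)
  theta_sum <- matrix(0, arr$N, K)
  steps <- c(0.4, 0.6)           # RW scales for (mu_I, logit eta_I)
  acc_count <- c(0, 0); prop_count <- 0
  rj_acc <- c(0, 0)
  for (it in seq_len(control$n_iter)) {
    if (up$theta) state <- update_theta(arr, state, hyper)
    if (up$gamma_tau) state <- update_gamma_tau(arr, state, hyper)
    if (up$rj) {
      state <- rj_update_indicators(arr, state, hyper)
      rj_acc <- rj_acc + attr(state, "rj_acc")
    }
    if (up$population) state <- update_population(arr, state, hyper)
    if (up$coupling) {
      mh <- mh_update_coupling(arr, state, hyper, steps)
      state <- mh$state
      acc_count <- acc_count + mh$accepted
      prop_count <- prop_count + 1
      if (control$adapt_mh && it <= control$burn_in && it %% 100 == 0) {
        rate <- acc_count / prop_count
        steps <- steps * exp(0.5 * (rate - 0.44))   # aim at ~0.44 accept
        steps <- pmin(pmax(steps, 0.02), 5)
        acc_count <- c(0, 0); prop_count <- 0
      }
    }
    if (it > control$burn_in) {
      j <- it - control$burn_in
      pop[j, ] <- c(state$mu_theta, state$sig2_theta, state$mu_gamma,
                    state$sig2_gamma, state$sig2, state$mu_I, state$eta_I)
      I_sum <- I_sum + state$I
      theta_sum <- theta_sum + state$theta
    }
  }
  ll <- sum(loglik_matrix(arr, state$theta, state$I,
                          exp(state$loggam), state$tau, state$sig2))
  if (!is.finite(ll)) {
    stop("non-finite log-likelihood at the end of the chain; state dump:\n",
         paste(utils::capture.output(utils::str(state)), collapse = "\n"))
  }
  list(pop = pop, I_mean = I_sum / kept, theta_mean = theta_sum / kept,
       final_state = state, seed = seed,
       mh_steps = steps,
       rj_accept_rate = if (rj_acc[2] > 0) rj_acc[1] / rj_acc[2] else NA_real_)
}

#' Fit the joint multivariable Bayesian change-point model
#'
#' Runs the full MCMC sweep per iteration: Gibbs updates of all conjugate
#' blocks (subject baselines, population means and variances, residual
#' variances), Metropolis-Hastings on the indicator-MRF parameters
#' \code{(mu_I, eta_I)}, a within-model refresh of each active slope and
#' change point, and a reversible-jump birth/death move on every case
#' indicator. Chains are initialized by sampling from the priors.
#'
#' @param cohort a \code{screening_cohort} with at least one control and one
#'   case.
#' @param markers optional marker subset (defines the joint model, e.g.
#'   \code{c("CA125","HE4")}).
#' @param hyper a \code{bcp_hyperparams}; defaults match the marker count.
#' @param control a \code{bcp_control}; defaults are the full-scale run
#'   (2 chains x 40,000 iterations, 5,000 burn-in).
#' @param seed integer seed; chain c uses a seed derived from it.
#' @return object of class \code{bcp_fit} with per-chain population-parameter
#'   draws (\code{chains}), posterior indicator probabilities
#'   (\code{I_mean}), subject baseline means, acceptance diagnostics,
#'   and the retained-sample bookkeeping.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(20, 10, seed = 1)
#' fit <- bcp_fit(coh, control = bcp_control(400, 100, 2), seed = 1)
#' summary(fit)
#' }
#' @export
bcp_fit <- function(cohort, markers = NULL, hyper = NULL,
                    control = bcp_control(), seed = 1L) {
  stopifnot(inherits(cohort, "screening_cohort"))
  arr <- cohort_arrays(cohort, markers)
  if (!any(arr$status == 0) || !any(arr$status == 1)) {
    stop("cohort must contain at least one control and one case")
  }
  hyper <- hyper %||% bcp_hyperparams(K = arr$K)
  if (hyper$K != arr$K) stop("hyperparameters are for ", hyper$K,
                             " markers but ", arr$K, " were requested")
  chains <- lapply(seq_len(control$n_chains), function(cc) {
    run_bcp_chain(arr, hyper, control, seed = derive_seed(seed, cc))
  })
  kept <- control$n_iter - control$burn_in
  I_mean <- Reduce(`+`, lapply(chains, `[[`, "I_mean")) / length(chains)
  theta_mean <- Reduce(`+`, lapply(chains, `[[`, "theta_mean")) / length(chains)
  dimnames(I_mean) <- dimnames(theta_mean) <- list(arr$ids, arr$markers)
  structure(list(
    chains = lapply(chains, `[[`, "pop"),
    I_mean = I_mean, theta_mean = theta_mean,
    control = control, retained = retained_samples(control),
    hyper = hyper, markers = arr$markers, seed = seed,
    n_controls = sum(arr$status == 0), n_cases = sum(arr$status == 1),
    rj_accept_rate = mean(vapply(chains, `[[`, numeric(1), "rj_accept_rate"))
  ), class = "bcp_fit")
}

#' Pool retained population-parameter draws across chains
#' @param fit a \code{bcp_fit}.
#' @return matrix (retained draws x parameters).
#' @export
pooled_draws <- function(fit) do.call(rbind, fit$chains)

#' @export
print.bcp_fit <- function(x, ...) {
  cat("Bayesian change-point model fit\n")
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  cat("  cohort:", x$n_controls, "controls,", x$n_cases, "cases\n")
  cat("  chains:", x$control$n_chains, "x", x$control$n_iter, "iterations (",
      x$control$burn_in, "burn-in ) ->", x$retained, "retained draws\n")
  invisible(x)
}

#' @export
summary.bcp_fit <- function(object, ...) {
  print(object)
  dr <- pooled_draws(object)
  qs <- t(apply(dr, 2, stats::quantile, c(0.05, 0.5, 0.95)))
  out <- data.frame(mean = colMeans(dr), sd = apply(dr, 2, stats::sd), qs,
                    rhat = gelman_rubin(object), check.names = FALSE)
  cat("Population parameters (posterior mean, sd, 5/50/95%, R-hat):\n")
  print(round(out, 4))
  invisible(out)
}

#' @export
coef.bcp_fit <- function(object, ...) colMeans(pooled_draws(object))

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (plain, non-rank) R-hat: for M chains of length n with
#' between-chain variance B and mean within-chain variance W,
#' \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}}.
#'
#' @param x a matrix (iterations x chains), a list of equal-length numeric
#'   chains, or a \code{bcp_fit} (then one R-hat per population parameter).
#' @param ... unused.
#' @return numeric R-hat value(s).
#' @export
gelman_rubin <- function(x, ...) UseMethod("gelman_rubin")

#' @export
gelman_rubin.default <- function(x, ...) {
  if (is.list(x)) {
    len <- unique(lengths(x))
    if (length(len) != 1) stop("chains must have equal length")
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("Gelman-Rubin needs at least 2 chains")
  n <- nrow(x); m <- ncol(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
gelman_rubin.bcp_fit <- function(x, ...) {
  if (length(x$chains) < 2) stop("Gelman-Rubin needs at least 2 chains")
  pars <- colnames(x$chains[[1]])
  vapply(pars, function(p) {
    gelman_rubin(vapply(x$chains, function(ch) ch[, p],
                        numeric(nrow(x$chains[[1]]))))
  }, numeric(1))
}
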