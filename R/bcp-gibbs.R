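# MCMC transition kernels for the change-point model.
#
# Conjugate full conditionals (derivations):
#  * theta_ik | rest: prior N(mu_theta_k, sig2_theta_k), likelihood
#    N(theta, sig2_k) around the hinge-adjusted observations
#    Y_ijk - I_ik gamma_ik (t - tau)_+.  Normal-normal:
#      prec = 1/sig2_theta + T_i/sig2_k,
#      mean = (mu_theta/sig2_theta + sum_j resid_j / sig2_k) / prec.
#  * mu_theta_k | theta: prior N(mu0, sig20), data theta_ik ~ N(mu_theta, sig2_theta),
#    the same normal-normal update with n = N.
#  * sig2_theta_k | theta, mu_theta: IG(a_theta + N/2,
#      b_theta + sum_i (theta_ik - mu_theta_k)^2 / 2).
#  * mu_gamma_k, sig2_gamma_k: same pair of updates on log gamma_ik over the
#    case-markers with I_ik = 1 (n may be 0: the draw is then from the prior).
#  * sig2_k: IG(a + n_obs/2, b + SSR_k/2) with SSR the hinge-adjusted
#    residual sum of squares over all patients and visits.
# Non-conjugate blocks:
#  * (mu_I, eta_I): random-walk Metropolis-Hastings on (mu_I, logit eta_I),
#    target = Beta priors x MRF likelihood of all case indicator vectors with
#    the exact 2^K normalizing constant; step sizes adapt during burn-in only.
#  * (log gamma_ik, tau_ik) given I_ik = 1: random-walk MH refresh.
#  * I_ik: reversible jump between the flat (I=0) and change-point (I=1)
#    spaces.  Birth proposes (gamma, tau) from their population priors, so
#    the Jacobian is 1 and the prior terms cancel: the acceptance ratio is
#    the likelihood ratio times the MRF conditional odds of I_ik.

# --- generic conjugate draws (shared by sampler and prior-limit tests) ----

# Normal mean with normal prior; data: n observations with sum `s`,
# each N(mean, data_var).  n = 0 returns a prior draw.
gibbs_normal_mean <- function(prior_mean, prior_var, s, n, data_var) {
  prec <- 1 / prior_var + n / data_var
  m <- (prior_mean / prior_var + s / data_var) / prec
  stats::rnorm(length(m), m, sqrt(1 / prec))
}

# Variance with IG(shape, scale) prior; data: n observations with residual
# sum of squares ss.  n = 0 returns a prior draw.
gibbs_invgamma_var <- function(prior_shape, prior_scale, ss, n) {
  rinvgamma(length(prior_shape), prior_shape + n / 2, prior_scale + ss / 2)
}

# --- sampler state ---------------------------------------------------------

# state: theta (N x K), I (N x K), loggam (N x K), tau (N x K),
#        mu_theta, sig2_theta, mu_gamma, sig2_gamma, sig2 (length K),
#        mu_I, eta_I (scalars)

draw_state_from_prior <- function(arr, hyper) {
  K <- arr$K; N <- arr$N
  mu_theta <- stats::rnorm(K, hyper$mu0, sqrt(hyper$sig20))
  sig2_theta <- rinvgamma(K, hyper$a_theta, hyper$b_theta)
  mu_gamma <- stats::rnorm(K, hyper$mu1, sqrt(hyper$sig21))
  sig2_gamma <- rinvgamma(K, hyper$a_gamma, hyper$b_gamma)
  sig2 <- rinvgamma(K, hyper$a, hyper$b)
  mu_I <- logit(stats::rbeta(1, hyper$p1, hyper$p2))
  eta_I <- stats::rbeta(1, hyper$p3, hyper$p4)
  theta <- matrix(stats::rnorm(N * K, rep(mu_theta, each = N),
                               rep(sqrt(sig2_theta), each = N)), N, K)
  I <- matrix(0, N, K)
  cases <- which(arr$status == 1)
  if (length(cases)) {
    I[cases, ] <- sample_indicators(length(cases), mu_I, eta_I, hyper$R, K)
  }
  loggam <- matrix(stats::rnorm(N * K, rep(mu_gamma, each = N),
                                rep(sqrt(sig2_gamma), each = N)), N, K)
  tau <- matrix(rtnorm(N * K, rep(arr$d - hyper$mu_tau, K),
                       sqrt(hyper$sig2_tau),
                       rep(arr$d - hyper$tau_star, K), rep(arr$d, K)), N, K)
  list(theta = theta, I = I, loggam = loggam, tau = tau,
       mu_theta = mu_theta, sig2_theta = sig2_theta,
       mu_gamma = mu_gamma, sig2_gamma = sig2_gamma, sig2 = sig2,
       mu_I = mu_I, eta_I = eta_I)
}

# hinge-adjusted observations for marker k: Y - I * gamma * (t - tau)_+
adjusted_Y_k <- function(arr, state, k) {
  Yk <- arr$Y[, , k, drop = FALSE]; dim(Yk) <- c(arr$N, arr$Tmax)
  act <- state$I[, k] == 1
  if (any(act)) {
    hinge <- pmax(arr$t[act, , drop = FALSE] - state$tau[act, k], 0)
    Yk[act, ] <- Yk[act, ] - exp(state$loggam[act, k]) * hinge
  }
  Yk
}

update_theta <- function(arr, state, hyper) {
  for (k in seq_len(arr$K)) {
    Yk <- adjusted_Y_k(arr, state, k)
    s <- rowSums(Yk, na.rm = TRUE)
    state$theta[, k] <- gibbs_normal_mean(
      rep(state$mu_theta[k], arr$N), rep(state$sig2_theta[k], arr$N),
      s, arr$Ti, rep(state$sig2[k], arr$N))
  }
  state
}

update_population <- function(arr, state, hyper) {
  K <- arr$K; N <- arr$N
  # population baseline mean / variance
  state$mu_theta <- gibbs_normal_mean(hyper$mu0, hyper$sig20,
                                      colSums(state$theta), rep(N, K),
                                      state$sig2_theta)
  ss <- colSums((state$theta - rep(state$mu_theta, each = N))^2)
  state$sig2_theta <- gibbs_invgamma_var(hyper$a_theta, hyper$b_theta, ss, rep(N, K))
  # population slope mean / variance over active case-markers
  act <- state$I == 1
  n_act <- colSums(act)
  s_lg <- colSums(state$loggam * act)
  state$mu_gamma <- gibbs_normal_mean(hyper$mu1, hyper$sig21, s_lg, n_act,
                                      state$sig2_gamma)
  ss_lg <- colSums(((state$loggam - rep(state$mu_gamma, each = N))^2) * act)
  state$sig2_gamma <- gibbs_invgamma_var(hyper$a_gamma, hyper$b_gamma, ss_lg, n_act)
  # residual variances
  for (k in seq_len(K)) {
    r <- adjusted_Y_k(arr, state, k) - state$theta[, k]
    ssr <- sum(r[arr$mask]^2)
    state$sig2[k] <- gibbs_invgamma_var(hyper$a[k], hyper$b[k], ssr, sum(arr$Ti))
  }
  state
}

# log target of (mu_I, eta_I) given the case indicator vectors
coupling_log_target <- function(mu_I, eta_I, Icases, hyper) {
  if (eta_I <= 0 || eta_I >= 1) return(-Inf)
  p <- plogis_(mu_I)
  lp <- stats::dbeta(p, hyper$p1, hyper$p2, log = TRUE) + log(p) + log1p(-p) +
    stats::dbeta(eta_I, hyper$p3, hyper$p4, log = TRUE)
  if (nrow(Icases)) {
    K <- ncol(Icases)
    lp <- lp + sum(mrf_log_potential(Icases, mu_I, eta_I, hyper$R)) -
      nrow(Icases) * mrf_log_normconst(mu_I, eta_I, hyper$R, K)
  }
  lp
}

mh_update_coupling <- function(arr, state, hyper, steps) {
  Icases <- state$I[arr$status == 1, , drop = FALSE]
  cur <- coupling_log_target(state$mu_I, state$eta_I, Icases, hyper)
  accepted <- c(mu_I = FALSE, eta_I = FALSE)
  # mu_I walk on its own (unbounded) scale
  mu_prop <- state$mu_I + stats::rnorm(1, 0, steps[1])
  prop <- coupling_log_target(mu_prop, state$eta_I, Icases, hyper)
  if (log(stats::runif(1)) < prop - cur) {
    state$mu_I <- mu_prop; cur <- prop; accepted[1] <- TRUE
  }
  # eta_I walk on the logit scale (Jacobian eta (1 - eta))
  z <- logit(state$eta_I) + stats::rnorm(1, 0, steps[2])
  eta_prop <- plogis_(z)
  prop <- coupling_log_target(state$mu_I, eta_prop, Icases, hyper) +
    log(eta_prop) + log1p(-eta_prop) -
    (log(state$eta_I) + log1p(-state$eta_I))
  if (log(stats::runif(1)) < prop - cur) {
    state$eta_I <- eta_prop; accepted[2] <- TRUE
  }
  list(state = state, accepted = accepted)
}

# per-patient marker-k log-likelihood under flat / hinge means, vectorized
# over a set of patients.  gam natural scale; rows = patients in `idx`.
loglik_k_rows <- function(arr, idx, k, theta_k, sig2_k, gam = NULL, tau = NULL) {
  r <- arr$Y[idx, , k, drop = FALSE]
  dim(r) <- dim(arr$t[idx, , drop = FALSE])
  r <- r - theta_k
  if (!is.null(gam)) {
    r <- r - gam * pmax(arr$t[idx, , drop = FALSE] - tau, 0)
  }
  ld <- stats::dnorm(r, 0, sqrt(sig2_k), log = TRUE)
  ld[!arr$mask[idx, , drop = FALSE]] <- 0
  rowSums(ld)
}

# Within-model refresh of (log gamma, tau) for active case-markers.
# Random-walk MH; the truncated-normal normalizer of tau's prior cancels,
# leaving the parent-normal density ratio (proposals outside the truncation
# interval have prior density zero and are rejected).
update_gamma_tau <- function(arr, state, hyper, step_lg = 0.3, step_tau = 0.3) {
  cases <- which(arr$status == 1)
  for (k in seq_len(arr$K)) {
    act <- cases[state$I[cases, k] == 1]
    if (!length(act)) next
    th <- state$theta[act, k]; s2 <- state$sig2[k]
    lg <- state$loggam[act, k]; tu <- state$tau[act, k]
    ll_cur <- loglik_k_rows(arr, act, k, th, s2, exp(lg), tu)
    # log gamma move
    lg_p <- lg + stats::rnorm(length(act), 0, step_lg)
    ll_p <- loglik_k_rows(arr, act, k, th, s2, exp(lg_p), tu)
    la <- ll_p - ll_cur +
      stats::dnorm(lg_p, state$mu_gamma[k], sqrt(state$sig2_gamma[k]), log = TRUE) -
      stats::dnorm(lg, state$mu_gamma[k], sqrt(state$sig2_gamma[k]), log = TRUE)
    acc <- log(stats::runif(length(act))) < la
    lg[acc] <- lg_p[acc]
    ll_cur[acc] <- ll_p[acc]
    # tau move (reject outside the truncation interval)
    tu_p <- tu + stats::rnorm(length(act), 0, step_tau)
    lo <- arr$d[act] - hyper$tau_star; hi <- arr$d[act]
    inside <- tu_p > lo & tu_p < hi
    ll_p <- loglik_k_rows(arr, act, k, th, s2, exp(lg), tu_p)
    la <- ll_p - ll_cur +
      stats::dnorm(tu_p, arr$d[act] - hyper$mu_tau, sqrt(hyper$sig2_tau), log = TRUE) -
      stats::dnorm(tu, arr$d[act] - hyper$mu_tau, sqrt(hyper$sig2_tau), log = TRUE)
    la[!inside] <- -Inf
    acc <- log(stats::runif(length(act))) < la
    tu[acc] <- tu_p[acc]
    state$loggam[act, k] <- lg
    state$tau[act, k] <- tu
  }
  state
}

# Reversible-jump move on every case indicator, marker by marker.
# Within one marker, patients are conditionally independent, so the
# birth/death decisions are vectorized across patients.
rj_update_indicators <- function(arr, state, hyper) {
  cases <- which(arr$status == 1)
  if (!length(cases)) return(state)
  W <- hyper$R + t(hyper$R)
  n_acc <- 0; n_prop <- 0
  for (k in seq_len(arr$K)) {
    th <- state$theta[cases, k]; s2 <- state$sig2[k]
    # MRF conditional log-odds of I_k = 1 given the other markers
    F_k <- state$mu_I +
      state$eta_I * (state$I[cases, , drop = FALSE] %*% W[, k] -
                       W[k, k] * state$I[cases, k])
    ll0 <- loglik_k_rows(arr, cases, k, th, s2)
    off <- state$I[cases, k] == 0
    # birth: propose (gamma, tau) from their population priors
    lg_new <- stats::rnorm(length(cases), state$mu_gamma[k],
                           sqrt(state$sig2_gamma[k]))
    tau_new <- rtnorm(length(cases), arr$d[cases] - hyper$mu_tau,
                      sqrt(hyper$sig2_tau),
                      arr$d[cases] - hyper$tau_star, arr$d[cases])
    lg_use <- ifelse(off, lg_new, state$loggam[cases, k])
    tau_use <- ifelse(off, tau_new, state$tau[cases, k])
    ll1 <- loglik_k_rows(arr, cases, k, th, s2, exp(lg_use), tau_use)
    # birth log-acceptance: likelihood ratio x conditional prior odds
    la <- ifelse(off, (ll1 - ll0) + F_k, (ll0 - ll1) - F_k)
    acc <- log(stats::runif(length(cases))) < la
    n_prop <- n_prop + length(cases); n_acc <- n_acc + sum(acc)
    newI <- ifelse(acc, 1 - state$I[cases, k], state$I[cases, k])
    born <- acc & off
    state$loggam[cases[born], k] <- lg_new[born]
    state$tau[cases[born], k] <- tau_new[born]
    state$I[cases, k] <- newI
  }
  attr(state, "rj_acc") <- c(n_acc, n_prop)
  state
}
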