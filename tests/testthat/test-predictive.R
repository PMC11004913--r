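# Posterior-predictive density and the Bayes screening rule.

frozen_draws <- function(S, markers = "M1",
                         mu_theta = 2, sig2_theta = 0.16, mu_gamma = 0,
                         sig2_gamma = 0.25, sig2 = 0.05,
                         mu_I = qlogis(0.85), eta_I = 0) {
  K <- length(markers)
  m <- matrix(rep(c(rep(mu_theta, K), rep(sig2_theta, K), rep(mu_gamma, K),
                    rep(sig2_gamma, K), rep(sig2, K), mu_I, eta_I), each = S),
              nrow = S)
  colnames(m) <- ocscreen:::pop_par_names(markers)
  m
}

test_that("control-hypothesis predictive equals the analytic Gaussian", {
  y <- c(2.3, 1.9); tt <- c(60, 61)
  d1 <- frozen_draws(10)
  hyper <- bcp_hyperparams(K = 1, mu0 = 2, R = matrix(0, 1, 1))
  got <- ocscreen:::pp_logdens_draws(d1, hyper, "M1", cbind(y), tt, 0)
  expect_equal(got, csmvn_ref(y - 2, 0.05, 0.16), tolerance = 1e-10)
})

test_that("case-hypothesis predictive matches 2-D quadrature", {
  y <- c(2.2, 2.8); tt <- c(60, 61); d <- 61
  hyper <- bcp_hyperparams(K = 1, mu0 = 2, R = matrix(0, 1, 1))
  dr <- frozen_draws(60000)
  got <- ocscreen:::pp_logdens_draws(dr, hyper, "M1", cbind(y), tt, 1,
                                     seed = 21)
  # quadrature: mixture over I, grid over (log gamma, tau)
  dens0 <- exp(csmvn_ref(y - 2, 0.05, 0.16))
  lg_grid <- seq(-3, 3, length.out = 241)
  tau_grid <- seq(d - 5, d, length.out = 281)
  f <- outer(lg_grid, tau_grid, Vectorize(function(lg, tau) {
    r <- y - 2 - exp(lg) * pmax(tt - tau, 0)
    exp(csmvn_ref(r, 0.05, 0.16) + dnorm(lg, 0, 0.5, log = TRUE) +
          ocscreen:::dtnorm(tau, d - 2, sqrt(0.75), d - 5, d, log = TRUE))
  }))
  dens1 <- sum(f) * diff(lg_grid[1:2]) * diff(tau_grid[1:2])
  ref <- log(0.15 * dens0 + 0.85 * dens1)
  expect_equal(got, ref, tolerance = 0.01)
})

test_that("flat series favor the control model, rising series the case model", {
  hyper <- bcp_hyperparams(K = 1, mu0 = 2, R = matrix(0, 1, 1))
  dr <- frozen_draws(4000)
  tt <- c(58, 59, 60, 61)
  flat <- cbind(c(2.0, 2.05, 1.95, 2.0))
  l0 <- ocscreen:::pp_logdens_draws(dr, hyper, "M1", flat, tt, 0, seed = 1)
  l1 <- ocscreen:::pp_logdens_draws(dr, hyper, "M1", flat, tt, 1, seed = 1)
  expect_gt(l0, l1)
  rise <- cbind(c(2.0, 2.1, 2.8, 3.8))
  l0r <- ocscreen:::pp_logdens_draws(dr, hyper, "M1", rise, tt, 0, seed = 1)
  l1r <- ocscreen:::pp_logdens_draws(dr, hyper, "M1", rise, tt, 1, seed = 1)
  expect_gt(l1r, l0r)
})

test_that("Bayes risk combination follows the closed form", {
  # equal densities: risk = prevalence
  expect_equal(risk_from_logdens(log(0.3), log(0.3), 0.07), 0.07)
  # worked ratio: densities (0.6, 0.2), prevalence 0.01
  expect_equal(risk_from_logdens(log(0.6), log(0.2), 0.01),
               0.6 * 0.01 / (0.2 * 0.99 + 0.6 * 0.01), tolerance = 1e-12)
  # overwhelming case evidence
  expect_equal(risk_from_logdens(500, 0, 0.01), 1)
  expect_error(risk_from_logdens(0, 0, 0), "prevalence")
})

test_that("risk scores are invariant to marker relabeling", {
  y <- rbind(c(2.2, 4.1, 3.4), c(2.6, 4.4, 3.8)); tt <- c(60, 61)
  markers <- c("A", "B", "C"); mu <- c(A = 2, B = 4, C = 3.5)
  make_draws <- function(S, mk) {
    dr <- frozen_draws(S, mk, eta_I = 0.4)
    for (m in mk) dr[, paste0("mu_theta.", m)] <- mu[[m]]
    dr
  }
  perm <- c(3, 1, 2)
  hyper <- bcp_hyperparams(K = 3, mu0 = unname(mu))
  hyper_p <- bcp_hyperparams(K = 3, mu0 = unname(mu[perm]))
  dr <- make_draws(30000, markers)
  dr_p <- make_draws(30000, markers[perm])
  l0 <- ocscreen:::pp_logdens_draws(dr, hyper, markers, y, tt, 0)
  l0p <- ocscreen:::pp_logdens_draws(dr_p, hyper_p, markers[perm],
                                     y[, perm], tt, 0)
  expect_equal(l0, l0p, tolerance = 1e-10)
  l1 <- ocscreen:::pp_logdens_draws(dr, hyper, markers, y, tt, 1, seed = 2)
  l1p <- ocscreen:::pp_logdens_draws(dr_p, hyper_p, markers[perm],
                                     y[, perm], tt, 1, seed = 3)
  expect_equal(l1, l1p, tolerance = 0.03)
})

test_that("predict.bcp_fit yields deterministic per-visit risk trajectories", {
  coh <- small_cohort(10, 6, seed = 41)
  fit <- bcp_fit(coh, control = bcp_control(300, 100, 1), seed = 6)
  r1 <- predict(fit, coh, prevalence = 0.1, n_draws = 100, seed = 3)
  r2 <- predict(fit, coh, prevalence = 0.1, n_draws = 100, seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$risk >= 0 & r1$risk <= 1))
  # one row per prefix of length >= 2
  nv <- coh$patients$n_visits
  expect_equal(nrow(r1), sum(nv - 1))
  # higher prevalence can only raise the risk
  r3 <- predict(fit, coh, prevalence = 0.3, n_draws = 100, seed = 3)
  expect_true(all(r3$risk >= r1$risk - 1e-12))
})
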