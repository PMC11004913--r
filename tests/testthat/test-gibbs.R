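# Full-conditional correctness: each conjugate draw is compared with a
# grid-normalized prior x likelihood density (KS distance over many draws),
# and with the prior itself in the no-data limit.

# Hand-built padded-array instance: M identical copies of one case patient
# with 2 visits, so one vectorized update yields M i.i.d. draws from the
# same full conditional.
stacked_case_arr <- function(M, y, tt, d) {
  list(Y = array(rep(y, each = M), c(M, length(y), 1)),
       t = matrix(tt, M, length(tt), byrow = TRUE),
       mask = matrix(TRUE, M, length(tt)),
       Ti = rep(length(tt), M), status = rep(1, M),
       d = rep(d, M), diagnosis_age = rep(d, M),
       ids = sprintf("S%05d", seq_len(M)), markers = "M1",
       N = M, Tmax = length(tt), K = 1)
}

test_that("no-data conditionals reduce to the priors", {
  set.seed(1)
  M <- 1e5
  mu_d <- ocscreen:::gibbs_normal_mean(rep(2, M), rep(0.25, M), rep(0, M), rep(0, M),
                            rep(1, M))
  expect_lt(abs(mean(mu_d) - 2), 3 * sqrt(0.25 / M))
  expect_lt(abs(sd(mu_d) - 0.5), 0.01)
  v_d <- ocscreen:::gibbs_invgamma_var(rep(3, M), rep(0.5, M), rep(0, M), rep(0, M))
  expect_lt(abs(mean(v_d) - 0.5 / 2), 0.01)      # IG mean b/(a-1)
  ref <- 1 / rgamma(M, 3, rate = 0.5)
  expect_lt(suppressWarnings(ks.test(v_d, ref)$statistic), 0.01)
})

test_that("theta full conditional matches the grid-normalized density", {
  set.seed(2)
  M <- 1e5
  y <- c(2.2, 2.9); tt <- c(60, 61); d <- 61
  arr <- stacked_case_arr(M, y, tt, d)
  state <- list(theta = matrix(0, M, 1), I = matrix(1, M, 1),
                loggam = matrix(log(0.9), M, 1), tau = matrix(60.4, M, 1),
                mu_theta = 2.0, sig2_theta = 0.16,
                mu_gamma = 0, sig2_gamma = 0.25, sig2 = 0.05,
                mu_I = 1.7, eta_I = 0.3)
  hyper <- bcp_hyperparams(K = 1, mu0 = 2, R = matrix(0, 1, 1))
  out <- ocscreen:::update_theta(arr, state, hyper)
  draws <- out$theta[, 1]
  grid <- seq(1, 4, length.out = 4001)
  shift <- 0.9 * pmax(tt - 60.4, 0)
  logd <- dnorm(grid, 2.0, 0.4, log = TRUE) +
    sapply(grid, function(g) sum(dnorm(y, g + shift, sqrt(0.05), log = TRUE)))
  expect_lt(ks_grid(draws, grid, exp(logd - max(logd))), 0.01)
})

test_that("population-mean conditional matches its grid density", {
  set.seed(3)
  M <- 1e5
  theta <- c(2.1, 2.5, 1.9, 2.3)                  # "data" for mu_theta
  mu0 <- 2; sig20 <- 0.25; sig2_theta <- 0.16
  draws <- ocscreen:::gibbs_normal_mean(rep(mu0, M), rep(sig20, M),
                             rep(sum(theta), M), rep(length(theta), M),
                             rep(sig2_theta, M))
  grid <- seq(1, 3.5, length.out = 4001)
  logd <- dnorm(grid, mu0, sqrt(sig20), log = TRUE) +
    sapply(grid, function(g) sum(dnorm(theta, g, sqrt(sig2_theta), log = TRUE)))
  expect_lt(ks_grid(draws, grid, exp(logd - max(logd))), 0.01)
})

test_that("variance conditional matches its grid density", {
  set.seed(4)
  M <- 1e5
  resid <- c(0.21, -0.35, 0.1, 0.02, -0.18)
  a <- 3; b <- 0.18
  draws <- ocscreen:::gibbs_invgamma_var(rep(a, M), rep(b, M),
                              rep(sum(resid^2), M), rep(length(resid), M))
  grid <- seq(1e-4, 1.5, length.out = 8001)
  logd <- (-(a + 1) * log(grid) - b / grid) +
    sapply(grid, function(v) sum(dnorm(resid, 0, sqrt(v), log = TRUE)))
  expect_lt(ks_grid(draws, grid, exp(logd - max(logd))), 0.01)
})

test_that("population update assembles the right sufficient statistics", {
  set.seed(5)
  coh <- toy_cohort_1marker(c(1.4, 1.5), c(59, 60), c(2.2, 2.8), c(60, 61))
  arr <- ocscreen:::cohort_arrays(coh)
  hyper <- bcp_hyperparams(K = 1, mu0 = 2, R = matrix(0, 1, 1))
  state <- list(theta = matrix(c(1.45, 2.1), 2, 1), I = matrix(c(0, 1), 2, 1),
                loggam = matrix(log(0.8), 2, 1), tau = matrix(60.5, 2, 1),
                mu_theta = 2, sig2_theta = 0.16, mu_gamma = 0,
                sig2_gamma = 0.25, sig2 = 0.05, mu_I = 1.7, eta_I = 0.3)
  draws <- replicate(4000, ocscreen:::update_population(arr, state, hyper)$mu_theta)
  # closed-form posterior of mu_theta given theta
  prec <- 1 / hyper$sig20 + 2 / state$sig2_theta
  m <- (hyper$mu0 / hyper$sig20 + sum(state$theta) / state$sig2_theta) / prec
  expect_lt(abs(mean(draws) - m), 4 * sqrt(1 / prec / 4000))
  expect_lt(abs(sd(draws) - sqrt(1 / prec)), 0.02)
})

test_that("large-n posterior of the population mean concentrates at the grand mean", {
  set.seed(6)
  M <- 2e4
  theta <- rnorm(500, 2.6, 0.3)
  draws <- ocscreen:::gibbs_normal_mean(rep(0, M), rep(100, M), rep(sum(theta), M),
                             rep(500, M), rep(0.09, M))
  expect_lt(abs(mean(draws) - mean(theta)), 0.005)
  expect_lt(sd(draws), 0.05)
})
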