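# LSTM numeric correctness: closed forms at zero weights, a hand-coded
# scalar oracle for the gate equations, masking invariance, gradient checks
# and the training contracts.

zero_head <- function(sumH) list(We = matrix(0, sumH, 1), be = 0)

test_that("zero weights give the closed-form step", {
  H <- 3
  w <- ocscreen:::new_channel_weights(H, zero = TRUE)
  cp <- matrix(c(0.5, -1, 2), 1, H)
  st <- lstm_step(matrix(0.3, 1, H), cp, y_in = 1.7, w)
  # all gates 0.5, candidate 0 -> c = 0.5 c_prev, h = 0.5 tanh(0.5 c_prev)
  expect_equal(st$c, 0.5 * cp)
  expect_equal(st$h, 0.5 * tanh(0.5 * cp))
  st0 <- lstm_step(matrix(0, 1, H), matrix(0, 1, H), 0.9, w)
  expect_equal(st0$h, matrix(0, 1, H))
  expect_equal(st0$c, matrix(0, 1, H))
})

test_that("one step matches a hand-coded scalar evaluation", {
  set.seed(51)
  H <- 2
  w <- ocscreen:::new_channel_weights(H)
  h0 <- matrix(rnorm(H), 1); c0 <- matrix(rnorm(H), 1); y <- 0.8
  st <- lstm_step(h0, c0, y, w)
  sig <- function(x) 1 / (1 + exp(-x))
  for (j in 1:H) {
    g <- tanh(sum(h0 * w$Uc[, j]) + y * w$Wc[1, j] + w$bc[1, j])
    ii <- sig(sum(h0 * w$Ui[, j]) + y * w$Wi[1, j] + w$bi[1, j])
    ff <- sig(sum(h0 * w$Uf[, j]) + y * w$Wf[1, j] + w$bf[1, j])
    oo <- sig(sum(h0 * w$Uo[, j]) + y * w$Wo[1, j] + w$bo[1, j])
    cj <- ff * c0[1, j] + ii * g
    expect_equal(st$c[1, j], cj, tolerance = 1e-10)
    expect_equal(st$h[1, j], oo * tanh(cj), tolerance = 1e-10)
  }
})

test_that("two-step forward with head matches the scalar oracle", {
  set.seed(52)
  H <- 1
  w <- ocscreen:::new_channel_weights(H)
  We <- matrix(0.7, 1, 1); be <- -0.2
  ys <- c(0.4, -1.1)
  s1 <- lstm_step(matrix(0, 1, 1), matrix(0, 1, 1), ys[1], w)
  s2 <- lstm_step(s1$h, s1$c, ys[2], w)
  ref <- 1 / (1 + exp(-(s2$h[1, 1] * We[1, 1] + be)))
  fw <- ocscreen:::forward_all(
    list(x = list(matrix(ys, 1, 2)), mask = matrix(TRUE, 1, 2)),
    list(w), list(We = We, be = be))
  expect_equal(unname(fw$risk), ref, tolerance = 1e-10)
})

test_that("zero network outputs risk one half", {
  H <- 4
  w <- ocscreen:::new_channel_weights(H, zero = TRUE)
  fw <- ocscreen:::forward_all(
    list(x = list(matrix(rnorm(6), 2, 3)), mask = matrix(TRUE, 2, 3)),
    list(w), zero_head(H))
  expect_equal(unname(fw$risk), c(0.5, 0.5))
})

test_that("appending masked steps never changes the output", {
  set.seed(53)
  H <- 3
  w1 <- ocscreen:::new_channel_weights(H)
  w2 <- ocscreen:::new_channel_weights(H)
  head_ <- list(We = matrix(rnorm(2 * H), 2 * H, 1), be = 0.1)
  x1 <- matrix(rnorm(8), 2, 4); x2 <- matrix(rnorm(8), 2, 4)
  mask <- rbind(c(TRUE, TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE, TRUE))
  base <- ocscreen:::forward_all(list(x = list(x1, x2), mask = mask),
                                 list(w1, w2), head_)
  pad <- cbind(mask, FALSE, FALSE)
  xp1 <- cbind(x1, 99, -99); xp2 <- cbind(x2, 5, 5)  # junk in padded slots
  padded <- ocscreen:::forward_all(list(x = list(xp1, xp2), mask = pad),
                                   list(w1, w2), head_)
  expect_equal(base$risk, padded$risk, tolerance = 1e-12)
})

test_that("cross-entropy loss matches hand arithmetic and clips", {
  expect_equal(cross_entropy_loss(c(1, 0), c(0.9, 0.2)),
               -0.5 * (log(0.9) + log(0.8)), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c(1, 0), c(0.5, 0.5)), log(2))
  expect_warning(l <- cross_entropy_loss(1, 1), "clipped")
  expect_true(is.finite(l))
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(54)
  H <- 2; N <- 3; Tt <- 3
  weights <- list(ocscreen:::new_channel_weights(H),
                  ocscreen:::new_channel_weights(H))
  head_ <- list(We = matrix(rnorm(2 * H, sd = 0.5), 2 * H, 1), be = 0.05)
  inp <- list(x = list(matrix(rnorm(N * Tt), N, Tt),
                       matrix(rnorm(N * Tt), N, Tt)),
              mask = rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE),
                           c(TRUE, FALSE, FALSE)),
              labels = c(1, 0, 1))
  lg <- ocscreen:::lstm_loss_grads(inp, weights, head_)
  loss_at <- function(weights, head_) {
    fw <- ocscreen:::forward_all(inp, weights, head_)
    mean(-(inp$labels * log(fw$risk) + (1 - inp$labels) * log(1 - fw$risk)))
  }
  eps <- 1e-6
  # every channel weight
  for (ch in 1:2) for (nm in names(weights[[ch]])) {
    M <- weights[[ch]][[nm]]
    for (idx in seq_along(M)) {
      wp <- weights; wp[[ch]][[nm]][idx] <- M[idx] + eps
      wm <- weights; wm[[ch]][[nm]][idx] <- M[idx] - eps
      num <- (loss_at(wp, head_) - loss_at(wm, head_)) / (2 * eps)
      ana <- lg$grads[[ch]][[nm]][idx]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
  # head
  for (idx in seq_along(head_$We)) {
    hp <- head_; hp$We[idx] <- hp$We[idx] + eps
    hm <- head_; hm$We[idx] <- hm$We[idx] - eps
    num <- (loss_at(weights, hp) - loss_at(weights, hm)) / (2 * eps)
    expect_equal(lg$gWe[idx], num, tolerance = 1e-4)
  }
  hp <- head_; hp$be <- hp$be + eps
  hm <- head_; hm$be <- hm$be - eps
  expect_equal(lg$gbe, (loss_at(weights, hp) - loss_at(weights, hm)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("training is deterministic, rejects degenerate input, and learns", {
  coh <- small_cohort(30, 20, seed = 55, mu_gamma = 0.5, sig2_gamma = 0.05)
  cfg <- lstm_config(hidden = 4, dropout = 0.2, epochs = 50)
  f1 <- lstm_fit(coh, config = cfg, seed = 7)
  f2 <- lstm_fit(coh, config = cfg, seed = 7)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$weights, f2$weights)
  # learns a separable problem
  expect_lt(f1$loss_trace[20], f1$loss_trace[1])
  f3 <- lstm_fit(coh, config = lstm_config(hidden = 4, dropout = 0,
                                           epochs = 120), seed = 8)
  expect_gt(f3$train_auc, 0.95)
  # degenerate single-class cohort
  ctrl_only <- simulate_cohort(8, 0, seed = 56)
  expect_error(lstm_fit(ctrl_only), "cases and controls")
})

test_that("scaler statistics come from the training split only", {
  coh <- small_cohort(20, 10, seed = 57)
  half <- subset_cohort(coh, coh$patients$patient_id[1:15])
  i_full <- ocscreen:::lstm_inputs(coh, coh$markers)
  i_half <- ocscreen:::lstm_inputs(half, coh$markers)
  expect_false(isTRUE(all.equal(i_full$scaler, i_half$scaler)))
  # applying a stored scaler reproduces the training transform
  i_reuse <- ocscreen:::lstm_inputs(half, coh$markers, scaler = i_full$scaler)
  expect_identical(i_reuse$scaler, i_full$scaler)
})

test_that("eval-mode prediction is a pure function of its inputs", {
  coh <- small_cohort(12, 8, seed = 58)
  fit <- lstm_fit(coh, config = lstm_config(hidden = 3, epochs = 15), seed = 9)
  r1 <- predict(fit, coh)
  r2 <- predict(fit, coh)
  expect_identical(r1, r2)
  expect_true(all(r1$risk > 0 & r1$risk < 1))
  expect_equal(nrow(r1), sum(coh$patients$n_visits - 1))
})
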