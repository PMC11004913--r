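test_that("stratified folds preserve class balance and partition the cohort", {
  coh <- simulate_cohort(180, 44, seed = 61)
  plan <- make_folds(coh, k = 5, reps = 2, seed = 1)
  expect_equal(length(plan$folds), 10)
  ids0 <- coh$patients$patient_id[coh$patients$status == 0]
  ids1 <- coh$patients$patient_id[coh$patients$status == 1]
  for (fd in plan$folds) {
    expect_equal(sum(fd$test %in% ids0), 36)
    expect_true(sum(fd$test %in% ids1) %in% c(8, 9))
    expect_length(intersect(fd$train, fd$test), 0)
  }
  for (r in 1:2) {
    tests <- unlist(lapply(plan$folds[sapply(plan$folds, `[[`, "rep") == r],
                           `[[`, "test"))
    expect_setequal(tests, coh$patients$patient_id)
    expect_equal(length(tests), n_patients(coh))   # no overlaps
  }
  expect_identical(plan, make_folds(coh, 5, 2, seed = 1))
  expect_error(make_folds(simulate_cohort(20, 3, seed = 1), k = 5), "at least")
})

test_that("AUC equals brute-force case-control pair counting", {
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.4, 0.5, 0.1)), 0.75)
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  set.seed(62)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.4))
    sc <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties sometimes
    brute <- mean(outer(sc[lab == 1], sc[lab == 0],
                        function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auc_score(lab, sc), brute, tolerance = 1e-12)
  }
  expect_equal(auc_score(rep(c(0, 1), 500), rep(0.5, 1000)), 0.5)
  expect_error(auc_score(rep(1, 4), runif(4)), "one class absent")
})

test_that("sensitivity at 90% specificity follows the cutoff definition", {
  lab <- c(rep(0, 10), rep(1, 3))
  sc <- c(seq(0, 0.9, by = 0.1), 1, 1, 1)
  r <- sensitivity_at_specificity(lab, sc, 0.90)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$threshold, 0.9)
  # exchangeable scores: sensitivity approximately the false-positive budget
  set.seed(63)
  lab2 <- rep(c(0, 1), c(2000, 2000))
  sc2 <- runif(4000)
  r2 <- sensitivity_at_specificity(lab2, sc2, 0.90)
  expect_lt(abs(r2$sensitivity - 0.1), 0.03)
  # monotone in the allowed false-positive rate
  r100 <- sensitivity_at_specificity(lab2, sc2, 1.0)
  expect_lte(r100$sensitivity, r2$sensitivity)
})

test_that("sensitivity threshold matches an exhaustive cutoff scan", {
  lab <- c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1)
  sc <- c(0.11, 0.52, 0.48, 0.33, 0.62, 0.25, 0.6, 0.71, 0.45, 0.95)
  for (spec in c(0.5, 0.8, 0.9, 1.0)) {
    got <- sensitivity_at_specificity(lab, sc, spec)
    cand <- sort(unique(c(sc, Inf)))
    ok <- cand[vapply(cand, function(th) mean(sc[lab == 0] < th) >= spec,
                      logical(1))]
    th <- min(ok)
    expect_equal(got$threshold, th)
    expect_equal(got$sensitivity, mean(sc[lab == 1] >= th))
  }
})

test_that("paired permutation p-values match exhaustive sign-flip enumeration", {
  a <- c(0.97, 0.95, 0.99, 0.92, 0.96, 0.98, 0.94, 0.97, 0.95, 0.96)
  b <- a - c(0.02, 0.01, 0.03, 0.01, 0.02, 0.015, 0.01, 0.02, 0.02, 0.01)
  r <- permutation_test_paired(a, b, n_perm = 500)
  expect_false(r$exact)
  rex <- permutation_test_paired(a, b, n_perm = 1024)
  expect_true(rex$exact)
  # all differences positive: only the identity assignment ties the mean
  expect_equal(rex$p, 1 / 1024)
  # sampled variant converges to the exact answer
  expect_lt(abs(r$p - rex$p), 0.02)
  # identical metrics: every assignment ties
  expect_equal(permutation_test_paired(a, a, n_perm = 1024)$p, 1)
  # swapping a and b complements the p-value up to ties
  d <- a - b
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  perm <- as.vector(signs %*% d) / 10
  p_fwd <- mean(perm >= mean(d) - 1e-12)
  p_rev <- mean(perm >= -mean(d) - 1e-12) # = P(perm <= mean under symmetry)
  expect_equal(permutation_test_paired(b, a, n_perm = 1024)$p,
               1 - p_fwd + mean(abs(perm - mean(d)) < 1e-12))
  expect_equal(rex$p + permutation_test_paired(b, a, 1024)$p,
               1 + mean(abs(perm - mean(d)) < 1e-12))
  expect_error(permutation_test_paired(numeric(0), numeric(0)), "no paired")
})

test_that("screening horizons pick the documented evaluation visit", {
  df <- rbind(
    data.frame(patient_id = "X", status = 1, visit_index = 1:3,
               age_years = c(58.8, 59.6, 60.4), marker = "M1",
               raw_level = c(10, 12, 30)),
    data.frame(patient_id = "C", status = 0, visit_index = 1:3,
               age_years = c(57, 58, 59), marker = "M1",
               raw_level = c(9, 9, 9)))
  coh <- as_cohort(df, diagnosis_age = c(X = 60.8))
  all_h <- screen_horizon(coh, 0)
  expect_equal(all_h$eval_visit[all_h$patient_id == "X"], 3)
  expect_equal(all_h$eval_visit[all_h$patient_id == "C"], 3)
  # 1y horizon: case visits lie 2.0, 1.2, 0.4 years before diagnosis
  h1 <- screen_horizon(coh, 1)
  expect_equal(h1$eval_age[h1$patient_id == "X"], 59.6)
  # controls truncate relative to their last visit
  expect_equal(h1$eval_age[h1$patient_id == "C"], 58)
  # beyond every visit: the patient drops out
  h6 <- suppressMessages(screen_horizon(coh, 6))
  expect_equal(nrow(h6), 0)
})

test_that("lead time is the earliest abnormal visit to diagnosis", {
  traj <- data.frame(age_years = c(57.5, 58.5, 59.5, 60.5),
                     risk = c(0.02, 0.30, 0.75, 0.9))
  expect_equal(lead_time(traj, 0.30, 61), 2.5)   # tie counts as abnormal
  expect_equal(lead_time(traj, 0.02, 61), 3.5)
  expect_true(is.na(lead_time(traj, 0.95, 61)))
})

test_that("contingency tables tally joint detections", {
  a <- c(P1 = TRUE, P2 = TRUE, P3 = FALSE, P4 = TRUE, P5 = FALSE)
  b <- c(P1 = TRUE, P2 = FALSE, P3 = FALSE, P4 = TRUE, P5 = TRUE)
  m <- contingency_table(a, b)
  expect_equal(unname(m), rbind(c(2L, 1L), c(1L, 1L)))
  same <- contingency_table(a, a)
  expect_equal(same[1, 2] + same[2, 1], 0L)
  onesided <- contingency_table(c(X = TRUE, Y = TRUE),
                                c(X = FALSE, Y = FALSE))
  expect_equal(unname(onesided), rbind(c(0L, 2L), c(0L, 0L)))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(64)
  lab <- rbinom(60, 1, 0.4); lab[1:2] <- c(0, 1)
  sc <- runif(60) + lab * 0.3
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE)))
  expect_equal(auc_score(lab, sc), ref, tolerance = 1e-12)
})
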