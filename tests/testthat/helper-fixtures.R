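# Shared fixtures: all built in code at test time.

# Small generated cohort (3 markers) for model-level tests.
small_cohort <- function(n0 = 20, n1 = 10, seed = 42, ...) {
  simulate_cohort(n_controls = n0, n_cases = n1, seed = seed, ...)
}

# Hand-built toy cohort: one control + one case, one marker, explicit levels
# given on the transformed scale (converted back to raw for the container).
toy_cohort_1marker <- function(y_control, t_control, y_case, t_case,
                               diagnosis_age = max(t_case)) {
  df <- rbind(
    data.frame(patient_id = "C1", status = 0,
               visit_index = seq_along(t_control), age_years = t_control,
               marker = "M1", raw_level = exp(y_control) - 4),
    data.frame(patient_id = "A1", status = 1,
               visit_index = seq_along(t_case), age_years = t_case,
               marker = "M1", raw_level = exp(y_case) - 4))
  as_cohort(df, diagnosis_age = c(A1 = diagnosis_age))
}

# Kolmogorov-Smirnov distance between draws and a density known on a grid.
ks_grid <- function(draws, grid, dens) {
  dx <- diff(grid)
  cdf <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * dx))
  cdf <- cdf / cdf[length(cdf)]
  s <- sort(draws)
  Fg <- stats::approx(grid, cdf, xout = s, yleft = 0, yright = 1)$y
  Fe <- seq_along(s) / length(s)
  max(abs(Fe - Fg))
}

# Batch-means standard error for a (possibly autocorrelated) chain mean.
batch_se <- function(x, n_batch = 100) {
  n <- length(x) %/% n_batch * n_batch
  bm <- colMeans(matrix(x[seq_len(n)], ncol = n_batch))
  stats::sd(bm) / sqrt(n_batch)
}

# Compound-symmetric Gaussian log density (independent oracle copy).
csmvn_ref <- function(r, sig2, sig2_th) {
  j <- length(r)
  S <- diag(sig2, j) + sig2_th
  -0.5 * (j * log(2 * pi) + determinant(S)$modulus[1] +
            drop(r %*% solve(S, r)))
}
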