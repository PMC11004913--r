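# ocscreen

Longitudinal multimarker screening models for early ovarian-cancer
detection.

Serial serum biomarkers — CA125, HE4 and glycodelin — drift upward in the
years before an ovarian-cancer diagnosis, while in healthy women they
fluctuate around stable subject-specific baselines. `ocscreen` implements
two model families that turn a woman's longitudinal marker history into a
per-visit probability of cancer, together with everything needed to compare
them under repeated stratified cross-validation: a synthetic-cohort
generator, ROC / sensitivity-at-specificity metrics, paired permutation
tests, screening horizons and lead-time statistics. It is aimed at
biostatisticians working on longitudinal screening algorithms.

## The models

**Bayesian change-point model (BCP).** On the transformed scale
`Y = log(Z + 4)`, controls follow `Y_ijk = theta_ik + eps_ijk` with
`eps ~ N(0, sigma_k^2)`. Cases carry a latent binary indicator `I_ik`; when
`I_ik = 1` the series gains a hinge after a latent change-point age
`tau_ik`:

    Y_ijk = theta_ik + gamma_ik (t_ij - tau_ik)_+ + eps_ijk

A patient's indicators across markers form a Markov random field,
`P(I) ∝ exp(mu_I Σ_k I_k + eta_I I' R I)`, so a change in one marker raises
the conditional odds of changes in the others. Hierarchical priors sit on
all subject and population parameters: normal / inverse-gamma conjugate
pairs for baselines, slopes and variances; a moment-matched Beta prior with
mean 0.85 and sd 0.05 on the logistic transform of `mu_I` (about 15% of
cases never show an increment); and a truncated-normal change-point prior
on `(d_i - 5, d_i)` centred 2 years before the last measurement. The
posterior is sampled by MCMC — Gibbs for every conjugate block,
Metropolis–Hastings for `(mu_I, eta_I)`, and a reversible-jump birth/death
move on every case indicator — with Gelman–Rubin convergence diagnostics.
A new patient is scored by Bayes' rule on the two posterior-predictive
densities combined with a population prevalence prior.

**Per-marker LSTM (RNN).** One LSTM channel per marker plus one consuming
the screening ages; the channels' last hidden states are concatenated,
passed through dropout and a sigmoid head. Training is full-batch Adam on
the cross-entropy loss with orthogonal/Glorot initialization, masking for
variable sequence lengths, and nested-CV tuning of hidden size and dropout.
The whole network, including backpropagation through time, is implemented
in base R and verified against numerical gradients.

## Worked example

```r
library(ocscreen)

coh <- simulate_cohort(n_controls = 20, n_cases = 10, seed = 1)
fit <- bcp_fit(coh, control = bcp_control(400, 100, 2), seed = 1)
fit
#> Bayesian change-point model fit
#>   markers: CA125, HE4, glycodelin
#>   cohort: 20 controls, 10 cases
#>   chains: 2 x 400 iterations ( 100 burn-in ) -> 600 retained draws

risks <- predict(fit, coh, prevalence = 0.1, n_draws = 200, seed = 1)
last <- risks[!duplicated(risks$patient_id, fromLast = TRUE), ]
lab  <- coh$patients$status[match(last$patient_id, coh$patients$patient_id)]
auc_score(lab, last$risk)
#> [1] 0.95
```

`risks` holds one probability per patient and visit prefix (predictions
start at the second visit); the AUC of 0.95 says that at this small
training scale the model already ranks 95% of case–control pairs
correctly on the cohort it was fitted to. `lstm_fit()` / `predict()` mirror
the same interface for the LSTM, and `run_experiment()` drives the full
scenario matrix — joint models m(1,2,3), m(1,2), m(1,3) against univariate
u(1), u(2), u(3) — across stratified 5-fold × 2 cross-validation, writing
`metrics.csv`, `summary.csv`, `leadtime.csv` and `contingency.json`.

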