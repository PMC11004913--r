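---
title: "Longitudinal multimarker screening: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal multimarker screening: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocscreen)
```

## The screening problem

Serum CA125, HE4 and glycodelin are measured annually in screening
programmes; in women who go on to be diagnosed with ovarian cancer these
markers tend to leave their personal baseline one to three years before
clinical diagnosis and rise until diagnosis. The statistical task is to
convert a short, irregular, multimarker history (2–5 visits) into a
probability of cancer at each screen, early enough to buy lead time.
`ocscreen` implements two complementary approaches — a generative
hierarchical change-point model and a discriminative recurrent network —
plus the evaluation machinery needed to compare them fairly on small
cohorts.

All modelling is done on the shifted-log scale `Y = log(Z + 4)`: marker
distributions are right-skewed, and the +4 offset keeps the transform
defined for the small negative values background-corrected assays can
produce.

## The Bayesian change-point model

For control `i` and marker `k`, `Y_ijk = theta_ik + eps_ijk`,
`eps ~ N(0, sigma_k^2)`. For cases a binary indicator `I_ik` selects
between the flat model and a hinge model with latent change point `tau_ik`
and log-normal slope `gamma_ik`:

`Y_ijk = theta_ik + gamma_ik (t_ij - tau_ik)_+ + eps_ijk`.

The indicators of one patient are coupled across markers by a Markov
random field with sparsity parameter `mu_I` and coupling `eta_I`; the
coupling matrix defaults to strictly-upper-triangular ones, so every marker
pair shares one coupling weight. With three markers the normalizing
constant is an exact 8-state enumeration, which the Metropolis–Hastings
step for `(mu_I, eta_I)` uses directly.

Priors: conjugate normal/inverse-gamma pairs on all baseline and slope
population parameters; `plogis(mu_I) ~ Beta(42.5, 7.5)` — moment-matched to
mean 0.85, sd 0.05, encoding that roughly 15% of cases never show a marker
increment, a rate assumed common to all markers; `eta_I ~ Beta(1, 1)` (the
literature gives no concrete values, so we keep it uninformative and
configurable); and `tau_ik ~ TN_(d_i-5, d_i)(d_i - 2, 0.75)` — the
truncated-normal parameters are those of the parent normal, the window
reflects an assumed 5-year preclinical duration, and the mass concentrates
about 2 years before the last measurement `d_i`.

### Sampler

One sweep updates, in order: subject baselines `theta_ik` (Gibbs,
normal–normal with hinge-adjusted observations), a within-model
random-walk refresh of `(log gamma_ik, tau_ik)` for active case-markers, a
reversible-jump birth/death move on every case indicator, the population
conjugate blocks, and the MH step on `(mu_I, eta_I)` (random walk on
`mu_I` and on `logit(eta_I)`, step sizes adapted toward a 0.44 acceptance
rate during burn-in only, then frozen so the chain stays Markovian). Each
full-conditional derivation is documented beside its implementation in
`R/bcp-gibbs.R` and checked against grid-normalized prior × likelihood
densities in the test suite.

The reversible-jump birth proposes `(gamma, tau)` from their population
priors. With prior proposals the Jacobian is 1 and all prior terms cancel,
leaving the likelihood ratio times the MRF conditional odds — the simplest
correct trans-dimensional kernel, and one that can be validated against
quadrature. Because the RJ move alone would only refresh `(gamma, tau)`
when a death/birth pair succeeds, the within-model random-walk refresh is
essential for mixing; the combined kernel's stationary indicator
probability is tested against a 2-D quadrature oracle on a frozen
one-patient instance.

Chains start from independent prior draws. Defaults follow the full-scale
protocol — 2 chains × 40,000 iterations with 5,000 burn-in, 70,000 retained
draws — while `bcp_control()` exposes reduced scales for desk work. The
convergence diagnostic is the classic Gelman–Rubin
between/within-chain variance ratio with the conventional 1.1 threshold
(configurable; the literature specifies the statistic but no cutoff).

### Screening rule

A new patient's series is scored by
`P(o=1 | Y) = P(Y|o=1) p / (P(Y|o=1) p + P(Y|o=0)(1-p))` where `p` is a
population prevalence prior. The predictive densities marginalize the
subject baseline analytically (each marker's prefix is a
compound-symmetric Gaussian given the population draw) and the indicator,
slope and change point by fresh population-level draws per retained MCMC
sample, averaged with log-sum-exp. The prevalence input is deliberately
user-supplied — a scalar, an age-band lookup table, or a function of age —
because published incidence tables are licensed data we do not embed;
ranking metrics (AUC, sensitivity at fixed specificity) are invariant to
the choice since the map from density ratio to risk is monotone.

## The LSTM classifier

Each selected marker, plus the screening-age sequence, feeds its own LSTM
channel (scalar input per step, standard candidate/input/forget/output
gates). The last hidden states are concatenated, dropout is applied to the
concatenation at train time only, and a sigmoid head yields the risk.
Standardization statistics come from the training split alone and travel
with the model; variable-length sequences are handled by carry-forward
masking, so appending padded steps never changes an output (a tested
invariant). Weights initialize from random orthogonal recurrent kernels and
Glorot-uniform input maps with zero biases; training is full-batch Adam on
the cross-entropy loss, deterministic given the seed. The analytic
backpropagation-through-time gradients agree with central-difference
numerical gradients to 1e-4 relative on masked multi-channel instances.

Hyperparameter tuning follows a nested design: the inner loop is
stratified 10-fold cross-validation with 3 repetitions over a grid of
hidden sizes and dropout rates, selecting the highest mean validation AUC
(ties break toward the smaller hidden size, then lower dropout). AUC is our
selection metric as the package's own choice — loss or accuracy could be
substituted via the same interface. Learning rate and epoch count are fixed
meta-parameters: the package default is `lr = 1e-3`, 100 epochs, while the
acceptance-scale experiments declare `lr = 5e-3`, 400 epochs, because
full-batch Adam on cohorts of ~50 patients needs larger steps and more
passes to reach its plateau than minibatch conventions suggest. Per-visit
risk trajectories come from forward passes on every prefix of at least two
visits; patients with fewer visits are skipped with a warning.

## The synthetic-cohort generator

The generator draws from exactly the hierarchy the change-point model
assumes, so every latent is recorded and parameter recovery is testable.
Its defaults emulate the nested case–control screening design the models
target: 180 controls / 44 cases; annual visits; cases carrying 2, 3 or 5
samples in proportion 10:10:24 and controls 4 or 5 in proportion 2:178;
entry ages uniform on 50–73 years so screening ages span the
trial-population range; baseline log-scale means 2.8 / 4.0 / 3.5 for
CA125, HE4 and glycodelin (population medians of ~12 U/mL, ~50 pmol/L and
~30 ng/mL — the source cohort's marginal distributions are not published,
so these come from reference ranges and remain configurable);
between-subject SD 0.4 and residual SD 0.3 log units; log-slope mean 0
(median slope 1 log-unit/year) with SD 0.5; change points truncated-normal
in the last 5 years with mode 2 years before the final screen; and a
marginal change-point rate of 0.85 per marker. With positive coupling
(`eta_I = 0.5` by default) the sparsity parameter is calibrated
numerically so the marginal stays at its target — with `eta_I = 0` the
calibration reduces exactly to `qlogis(0.85)`. Diagnosis age defaults to
the last screen (a configurable gap is provided, as the screen-to-diagnosis
interval is not part of the generative model).

What the generator does **not** emulate: assay batch effects, informative
visit dropout, age-dependent baselines, non-Gaussian noise, or multiple
change points per series. Tests passing on generated cohorts therefore
certify the algorithms — samplers targeting the right posterior, metrics
matching their oracles, the multimarker-versus-univariate ordering under a
genuine two-marker signal — not performance on real trial data, whose
marginals and missingness patterns differ.

## Evaluation layer

Performance is estimated by stratified 5-fold cross-validation with two
repetitions; each test fold preserves the case fraction to within one
patient. AUC uses the rank (Mann–Whitney) formulation with half-credit for
ties and is tested against brute-force pair counting. Sensitivity at 90%
specificity takes the smallest cutoff achieving the target specificity on
the fold's test controls (ties at the threshold score as abnormal — the
"≥" convention); the test-side choice is configurable to train-side, which
the underlying protocol leaves unstated. Model comparisons use one-sided
sign-flip permutation tests on paired per-fold differences, enumerated
exactly (2^10 assignments for 10 folds) whenever the budget allows.
Screening horizons evaluate each case at its last visit at least h years
before diagnosis; controls, which have no diagnosis date, are truncated by
calendar years before their last visit — a declared convention. Lead time
is the interval from the earliest visit whose risk reaches the fold's 90%
specificity threshold to diagnosis, with never-flagged cases excluded;
fold-level summaries carry normal-approximation 95% CIs across the 10 fold
values (a bootstrap could be slotted in; with 10 values the normal
approximation is the transparent default).

## Numerical choices and problem sizes

Truncated-normal draws use the inverse-CDF method (bounds sit within ~4 SD
of the parent mean, where `qnorm` is accurate). Log-density averaging uses
log-sum-exp throughout. Cross-entropy inputs exactly at 0 or 1 are clipped
at 1e-7 with a warning. Degenerate conjugate updates (no active
case-markers, empty folds) fall back to prior draws rather than dividing
by zero. The test suite's problem sizes are the package's own desk-scale
choices: recovery runs use 60 patients with 2 × 4,000 iterations;
interval-coverage checks use 20 replicates of 24 patients at 1,200
iterations; the directional cross-validated comparison uses 64 patients,
700-iteration fits and 400-epoch LSTM training. Full-scale defaults
(40,000 iterations, 180/44 cohorts) remain one argument away.

## Known limitations

- `(mu_I, eta_I)` are shared across markers, following the joint MRF form;
  the alternative reading (marker-specific coupling) is not supported, and
  per-marker change-point rates are likewise not supported.
- The exact MRF normalizing constant limits the panel to 12 markers.
- Single change point per series, linear post-change drift, Gaussian
  noise; no missing-marker imputation.
- The LSTM is single-layer per channel, CPU-only, and trained full-batch;
  class weighting is not implemented.
- Lead-time and contingency summaries pool each case once per
  cross-validation repetition, so pooled counts are multiples of the case
  count.
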