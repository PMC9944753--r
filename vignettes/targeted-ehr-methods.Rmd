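---
title: "Targeted learning of SBP–cardiovascular risk ratios from simulated EHR cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted learning of SBP–cardiovascular risk ratios from simulated EHR cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrtmle)
```

## The scientific problem

Observational studies of systolic blood pressure (SBP) and cardiovascular
outcomes in patients with diabetes often report a *J-shaped* association: the
lowest SBP categories appear to carry elevated risk, with a nadir somewhere
around 130–139 mm Hg. A leading explanation is residual confounding and
reverse causation — frail, multimorbid patients tend to have *low* blood
pressure and *high* cardiovascular risk, and the handful of expert-selected
covariates available to a conventional regression does not capture that
frailty. A model that can read the patient's entire coded
diagnosis/medication history, combined with a doubly-robust targeted
estimator, may adjust away that distortion and recover the monotone
dose–response that randomized evidence supports.

`ehrtmle` implements that full argument as a reproducible pipeline on
synthetic data with known causal ground truth:

1. **`sim_config()` / `generate_population()`** — a longitudinal EHR
   simulator in which a latent frailty confounds SBP and outcome, with every
   patient's potential risks under all six exposure categories stored.
2. **`build_cohort()`** — the observational study design: entry at the first
   qualifying BP measurement, 12-month baseline exposure averaging, six SBP
   categories, exclusions, a composite outcome over months 12–120, and the
   sensitivity-analysis variants.
3. **`train_crossfit()`** — a compact transformer over coded histories
   trained jointly on a masked-sequence objective, a propensity head and two
   arm-specific outcome heads, cross-fitted over 5 folds.
4. **`cv_tmle_rr()`** — cross-validated targeted maximum likelihood
   estimation of the marginal risk ratio with influence-curve CIs.
5. **`crude_rr()` / `mice_impute()` / `adjusted_lr_rr()` /
   `cox_hazard_check()`** — the conventional comparators.
6. **`run_pipeline()` / `render_forest_table()`** — orchestration and
   forest-table reporting.

## The estimand and the estimator

For each comparison category $a \in \{1,\dots,5\}$ versus the reference
($<120$ mm Hg), restrict to patients in the two categories and let $A=1$
indicate the comparison arm, $Y$ the binary outcome (any composite event in
months 12–120), and $X$ the pre-entry history. The estimand is the marginal
risk ratio

$$\mathrm{RR}_a = \frac{\mathbb{E}_X[\,Q(1, X)\,]}{\mathbb{E}_X[\,Q(0, X)\,]},
\qquad Q(a, X) = \Pr(Y = 1 \mid A = a, X).$$

Initial nuisance estimates — the propensity $g(X)=\Pr(A=1\mid X)$ and the
outcome regressions $Q(1,X), Q(0,X)$ — are produced on held-out folds
(cross-fitting: each patient is predicted by a model that never saw them).
The targeting step fits a single fluctuation coefficient $\varepsilon$ by
maximum likelihood in the offset-logistic submodel

$$\operatorname{logit} Q_\varepsilon(A, X) = \operatorname{logit} Q(A, X)
  + \varepsilon H(A, X), \qquad
  H(A, X) = \frac{A}{g(X)} - \frac{1-A}{1-g(X)},$$

solved by Newton iterations until the empirical score
$\frac1n\sum_i H_i (Y_i - Q_\varepsilon)$ is below $10^{-12}$ (the test suite
verifies agreement with a brute-force likelihood maximization to $10^{-6}$
and a post-targeting score residual below $10^{-8}$). Targeted predictions
are standardized over *all* patients in the contrast, and the 95% CI comes
from the empirical variance of the efficient influence curve of
$\log\mathrm{RR}$, using the normal quantile 1.96. With $\varepsilon$ forced
to zero the estimator reduces exactly to the g-computation plug-in, which the
tests assert.

Design choices where the method description was genuinely open, and why:

* **Pairwise binary contrasts.** Each category is compared with the
  reference on the two-category subset with a binary propensity head, which
  matches the reported "each category vs <120" framing and keeps positivity
  diagnosable per contrast. A multiclass propensity would pool information
  across arms but complicate truncation; it is not implemented.
* **Pooled-fold fluctuation.** One $\varepsilon$ is fit on the pooled
  held-out predictions (default); per-fold targeting with pooled targeted
  predictions is available via `variant = "per_fold"`. Pooling is more
  stable at the cohort sizes used here; the two agree asymptotically.
* **Ratio of targeted means.** We target the two marginal risks and take
  their ratio (delta-method CI on the log scale) rather than targeting
  $\log \mathrm{RR}$ directly; at these event rates the two are numerically
  indistinguishable and the ratio form keeps the per-arm risks reportable.
* **One- vs two-dimensional fluctuation.** The default single-$\varepsilon$
  submodel updates both arms with one coefficient; `two_dim = TRUE` fits
  separate per-arm coefficients (the likelihood separates over arms).
* **Propensity truncation** at $\delta = 0.01$ guards positivity; the
  truncation bound is configurable and all clipped values are reported via
  the nuisance tables.

## The sequence model

The transformer is deliberately compact: token, age (integer years 0–110),
visit-segment (parity) and visit-position embeddings; post-layer-norm
encoder blocks with multi-head attention and GELU feed-forward; a pooled
`[CLS]` state feeding the propensity and the two arm-specific outcome heads;
and a masked-sequence head over corrupted code tokens (15% selection;
80/10/10 mask/random/keep). Histories are grouped into visits by calendar
day, separated by `[SEP]`, prefixed by `[CLS]` + sex + smoking tokens, and
truncated to the most recent `max_len` tokens. Defaults (2 layers, 4 heads,
hidden 96, `max_len` 256, loss weights 1, up to 10 epochs with early
stopping on a 10% inner split by propensity+outcome loss) are desk-scale
choices — the original architecture's hyperparameters are not public, and we
make no attempt to guess them; everything is configurable. Masked-sequence
learning can be run as a separate pretraining phase (`pretrain_epochs`) or
co-trained (default).

The implementation is plain R matrix algebra with hand-derived analytic
gradients and Adam. The backward pass is validated against central finite
differences in the test suite, and training behaviour is checked on
designed corpora: held-out propensity calibration under randomized exposure,
held-out AUC > 0.95 when a single code determines exposure, and masked-code
recovery above the marginal-frequency baseline on a corpus with
deterministic pair co-occurrence. Fresh vocabularies are built from each
training fold only, so codes unseen in training map to `[UNK]` at prediction
time.

Because transformer training is the pipeline's expensive stage, the
package also provides `crossfit_glm_nuisances()` — cross-fitted logistic
regressions on history-derived cohort features under the identical
cross-fitting contract — used as the fast nuisance engine for simulation
studies and calibration experiments. `history_glm_features()` deliberately
excludes baseline treatment flags: they predict exposure far better than
outcome, and such instrument-like covariates amplify residual confounding
bias in propensity-based estimators.

## What the simulator emulates — and what it does not

Each patient carries a latent frailty $U \sim N(0,1)$ that raises the
outcome log-odds (`conf_strength`), shifts the patient-specific mean SBP by
`sbp_conf_slope` mm Hg per SD (negative in the J-shape scenario: frail
patients run low pressures), inflates the Poisson recording rates of five
designated comorbidity codes and of background codes (`hist_u_slope`,
reflecting that frail patients contact care more often), and loads weakly on
BMI, atrial fibrillation and chronic kidney disease. Exposure is realized
from the *generating* SBP mean, while the analyst only sees noisy repeated
measurements (SD 10 mm Hg), so adjacent-category misclassification arises
naturally and is mitigated — exactly as in the emulated design — by
averaging the first year's measurements. Potential outcomes under all six
categories are drawn *before* exposure realization from a shared uniform, so
exchangeability holds by construction and permuting realized categories
cannot alter the stored potential risks. Dropout and non-cardiovascular
death are ignorable by default (`frailty_dropout = TRUE` adds
frailty-dependent censoring to probe the binary-outcome framework's
limitation). Prior heart failure and exposure-period events — the exclusion
pathways — are generated independently of frailty so that eligibility does
not shift the estimand.

Default rates were fixed once at values a UK primary-care diabetes cohort
makes plausible: event percentage near one third and censoring near a
quarter over the 9-year window, entry ages centred at 65, 45% women, 39%
ever-smokers, roughly 4 SBP measurements per year, MCAR covariate
missingness of 10–20% (45.1% for HbA1c). The simulator does **not** emulate
realistic clinical coding systems, practice-level clustering, diastolic
pressure, calendar trends, or informative measurement timing; passing tests
therefore demonstrate the estimator's behaviour under designed confounding,
not performance on real records.

The **J-shape scenario** (`sim_config_jshape()`) fixes a monotone true
gradient (category log-odds effects 0, 0.2, 0.5, 0.9, 1.5, 2.3) against a
frailty that lowers SBP by 14 mm Hg per SD while raising outcome log-odds
by 1.0. The effect gaps were chosen to dominate the *residual* confounding
left after history adjustment at every category — including the extremes,
where tail enrichment makes the confounding gradient steepest — while the
*full* confounding gradient still exceeds the low-end effect gaps, so crude
and covariate-only analyses dip below 1 with an interior minimum. The
demonstration uses cohorts of 20 000 simulated patients, the scale at which
the generator's own Monte-Carlo checks run; the shape diagnostics
(`rr_shape()`) are: interior minimum of the sequence $(1, RR_1..RR_5)$ for
the J-shape, and monotone non-decrease of the five estimated contrasts for
its absence.

## Numerical conventions and degenerate inputs

* Time is an integer day index (day 0 = 1990-01-01); years are 365.25 days,
  "12 months" is 365 days, "120 months" is 3650 days. The exposure-averaging
  window is half-open `[entry, entry+365)`; an event *at* day `entry+365`
  belongs to the exposure period (exclusion), and the outcome window is
  `(entry+365, entry+3650]` — the three windows partition the line, which
  the boundary tests pin down.
* SBP categories are half-open `[edge, edge+10)` bins: 120.0 is category 1,
  160.0 is category 5; cleaning retains the bounds 50 and 300 exactly and
  drops only strictly-outside values.
* Exclusion reasons are assigned with fixed precedence (prior HF → event →
  dropout) so the patient-flow accounting is deterministic; the flow always
  balances exactly and is fuzz-tested.
* Stratified fold assignment deals a seeded within-category permutation
  round-robin, so per-category fold counts differ by at most 1.
* The fluctuation solve damps Newton steps at extreme clever-covariate
  values, errors explicitly after 100 iterations, and refuses degenerate
  inputs (single-class arms or outcomes). Initial predictions are bounded
  away from 0/1 by $10^{-9}$ before the offset logit.
* Separation in a comparator logistic fold triggers a ridge refit
  (`glmnet`, $\alpha = 0$, $\lambda = 0.01$) with a warning.
* All randomness is seeded; every stochastic function restores the caller's
  RNG state, and the pipeline fans one global seed out to per-stage seeds by
  a fixed Lehmer step, so reruns are bit-identical.

## Comparator conventions

The adjusted logistic comparator standardizes fold-held-out predictions
(exposure forced to each arm), averages the five fold RRs across
imputations, and builds its CI from the dispersion of the fold log-RRs
(normal approximation, `mean ± 1.96 · SD/√5`) combined with
between-imputation variance by a Rubin-style rule; since published
descriptions of "CI over the 5 runs" rarely pin the formula down, the
fold-variance-only interval is reported alongside (`ci_fold_only`).
Chained-equation imputation (default m = 25 at full scale; smaller in the
worked examples) uses Bayesian linear draws for continuous covariates and
multinomial-logistic draws for smoking, with exposure category and outcome
always included as predictors; it is implemented in-package. The Cox check
is `survival::coxph` (Efron ties) on follow-up time from the end of the
exposure period, with `survival::cox.zph` scaled-Schoenfeld diagnostics
exported for plotting. Crude RRs use the textbook log-variance
`1/a − 1/n₁ + 1/c − 1/n₀`; forest tables show no CI for crude or reference
rows, matching the reporting convention of the emulated study.

## Known limitations

* The binary-outcome framework treats censored-without-event patients as
  non-events; with frailty-dependent dropout enabled this is biased, and the
  package demonstrates rather than repairs it (no survival-time targeting).
* History-based adjustment removes only the confounding that the coded
  history carries; with the default (weaker) frailty footprint roughly half
  of the crude bias remains, which the acceptance report shows honestly.
* The transformer is desk-scale; no GPU, no pretrained weights, no
  calendar-year inputs.
* Problem sizes in the test suite (hundreds to a few thousand patients for
  unit behaviour, 20 000 per replicate for the shape demonstration, 50
  calibration replicates at n = 2000) were chosen as the smallest scales at
  which the corresponding statistical properties are stable.
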