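---
title: "Normative gait waveform modelling with gaitnorm: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative gait waveform modelling with gaitnorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitnorm)
```

## The problem

Clinical assessment of a patient's walking pattern needs a normative
reference: the waveform a healthy person with the same sex, age,
anthropometry and walking characteristics would be expected to produce.
`gaitnorm` fits function-on-scalar regression models that predict sixteen
lower-limb kinematic and kinetic waveforms — joint angles (deg), ground
reaction forces (N/kg), joint moments (Nm/kg) and joint powers (W/kg), each
time-normalised to 100 points of the gait cycle — from seven scalar
covariates: sex, age, walking speed, body mass, height, cadence and side.

## The model

For outcome trajectory $y_i(t)$ of observation $i$ at gait-cycle point
$t \in \{0, \dots, 99\}$ the package fits, independently per outcome,

$$
y_i(t) = \beta_0(t) + f_{age}(a_i, t) + f_{speed}(v_i, t) +
         f_{cad}(c_i, t) + f_{ht}(h_i, t) + f_{mass}(m_i, t) +
         \beta_{sex}\,\mathbb{1}[\text{female}_i] +
         \beta_{side}\,\mathbb{1}[\text{right}_i] + b_{s(i)}(t) + \varepsilon_i(t),
$$

with $\varepsilon_i(t) \sim N(0, \sigma^2)$ i.i.d. across grid points and
observations, and $b_s(t)$ a smooth subject-level random intercept curve
capturing within-subject correlation across a subject's repeated
observations (three walking-speed conditions).

**Estimation.** All terms are represented with B-splines:

* $\beta_0(t)$ and each $b_s(t)$ on a cubic 20-dimensional basis over the
  cycle;
* each bivariate surface $f(x, t)$ as an 8 × 8 tensor product of cubic
  marginal bases, with one second-order difference penalty per marginal
  direction (anisotropic smoothing);
* $b_s(t)$ coefficients under a shared ridge penalty, making the predicted
  subject curves BLUPs of a working random-effects model.

The stacked system (one row per observation × grid point) is solved by
penalized least squares, $\min_\beta \|y - X\beta\|^2 + \sum_k \lambda_k
\beta^\top P_k \beta$, using sparse Cholesky factorisations (`Matrix`).
Smoothing parameters are chosen by optimizing the profiled restricted
likelihood (REML, default) or GCV over $\log \lambda$ with Nelder–Mead;
fixed $\lambda$ vectors can be supplied for exact reproducibility.
The coefficient covariance is the Bayesian posterior
$\hat\sigma^2 (X^\top X + \sum_k \lambda_k P_k)^{-1}$ (fixed-effect block
retained densely), and $\hat\sigma^2$ is the penalized residual sum of
squares divided by $n \cdot 100 - \text{edf}$.

**Identifiability.** Each $f(x, t)$ carries a sum-to-zero constraint over
the *empirical training covariate values at each $t$*: the constraint
matrix couples only the covariate margin, so it is absorbed exactly by a
QR null-space reparametrisation of that margin (7 of 8 marginal
coefficients remain). Consequently the time-varying intercept estimates
$\beta_0(t)$ *plus* the finite-sample mean of the centred covariate
surfaces — the usual convention in functional additive models, and the
target used by the calibration tests. Sex and side are coded male = 0 /
female = 1 and left = 0 / right = 1; the male-left baseline is absorbed by
$\beta_0(t)$.

## Prediction and uncertainty

`predict_mean()` evaluates the population-level curve for a new covariate
profile with $b_s(t) = 0$ — the normative curve for an unseen individual.
`predict_band(kind = "ci")` adds the pointwise Wald band
$\pm z_{1-\alpha/2}\,\mathrm{se}(t)$ from the coefficient covariance;
`kind = "sd"` reports a population-spread band with
$\mathrm{sd}(t)^2 = \text{prediction variance} + \mathrm{Var}(b(t)) +
\hat\sigma^2$, i.e. the expected spread of individual observed curves
around the normative mean. Bands are pointwise, not simultaneous — they
match the per-point "error cloud" style of normative plots; a simultaneous
band would be wider.

Covariates outside the training range (extended 1% per side) are refused
rather than extrapolated: B-spline fits carry no information beyond their
knots. `extract_smooth_effect()` returns $\hat f(x, t)$ with pointwise 95%
CIs at chosen covariate values, defaulting to the training 25th/50th/75th
quantiles (linear-interpolation quantile definition, R type 7).

## Evaluation design

Validation splits are by participant (all observations of a subject stay
together): `split_participants()` assigns `floor(0.8 n)` subjects to
training. Three curve-level metrics compare an observed and a predicted
waveform:

* RMSE — root mean squared pointwise difference over the evaluation
  window (rectangle-rule discretisation of the integrated squared error);
* relRMSE — RMSE divided by the mean of the two curve ranges, in percent;
  undefined (an error) when both curves are constant;
* Pearson correlation — `NA` (excluded from aggregation, counted) when a
  curve has zero variance.

The default window is the full 100-point cycle. The integral in the
metric's definition is sometimes taken over stance only; the data here are
normalised over the full cycle, so the full cycle is the default and a
`window` argument restricts to any sub-window (e.g. stance) when wanted.
Reports aggregate mean (SD) per outcome across test curves, the standard
presentation of normative-model accuracy tables. If a held-out subject's
covariate falls marginally outside the supported range, `evaluate_model()`
clamps it to the boundary and reports the count (`n_clamped`); the CLI
avoids the situation by deriving covariate domains from the full table
before splitting.

## The synthetic cohort generator

`sample_covariates()` and `generate_cohort()` emulate a lifespan treadmill
cohort so the whole pipeline is testable without any data download:

* ages uniform on [3, 91] years; below 18, height follows a growth curve
  toward a sex-specific adult height and mass follows an age-dependent BMI;
* comfortable walking speed rises through childhood and declines after 60;
  each subject walks at exactly 0.7×, 1.0× and 1.3× comfortable speed
  (slow / comfortable / fast conditions);
* cadence = 60·speed / (0.414·height·pref) + noise, with a person-specific
  step-length preference pref ~ N(1, 0.07). The preference term matters:
  without it cadence is almost a deterministic function of speed and
  height (r ≈ 0.97) and the speed and cadence surfaces are not separately
  identifiable — an early version of the generator had exactly this defect
  and the fitted speed surface could not reach its recovery target at any
  sample size;
* side alternates across a subject's observations (one curve per
  subject × speed condition, so 240 subjects yield 720 observations);
* the truth has a two-bump intercept shaped like a hip-flexion trace, an
  age surface quadratic in age with its turning point at 48 years, a speed
  surface monotone in log-speed and largest early in the cycle, smaller
  cadence/height/mass surfaces, scalar sex and side offsets, smooth
  subject intercept curves (6-dim spline basis, pooled curve SD
  `sigma_b`), and i.i.d. Gaussian grid-point noise `sigma_eps`. All
  surfaces are numerically centred over their covariate sampling range.
  Default amplitudes scale by outcome family (≈30 deg angles, 10 N/kg
  vertical GRF, 2 N/kg AP GRF, 1.5 Nm/kg moments, 3 W/kg powers), with
  `sigma_eps` = 5% and `sigma_b` = 8% of the amplitude.

What the generator does *not* emulate: heteroscedastic or temporally
correlated measurement noise, asymmetry between sides beyond a constant
offset, outcome-to-outcome correlation within a subject, marker/model
artefacts, or non-Gaussian tails. A green test therefore establishes that
the estimation and uncertainty machinery is correct under the stated
model, not that real gait data satisfy that model.

## Numerical choices

* Marginal B-splines are evaluated with `splines::splineDesign` on
  equally spaced interior knots with full boundary-knot multiplicity;
  points at the right boundary are nudged one part in 10^12 inward so the
  last basis function keeps its value there. Tests verify against an
  independent de Boor recursion.
* REML per evaluation costs one sparse Cholesky update; the pseudo
  log-determinant of the total penalty decomposes over blocks (small
  eigenproblems; ridge blocks in closed form). Effective degrees of
  freedom use $\mathrm{tr}(A^{-1} S) = \|L^{-1} P R\|_F^2$ with a
  blockwise square root $S = RR^\top$, so GCV is practical for modest
  designs and REML for large ones.
* Nelder–Mead runs on $\log\lambda$ from a scale-matched start
  ($\mathrm{tr}(X^\top X)_{block} / \mathrm{tr}(P_k)$); convergence codes
  1 (iteration cap) and 10 (simplex degeneracy) are accepted as usable
  optima, anything else raises an error carrying the evaluation trace.
  Log-lambdas are confined to ±50 to keep the factorisation finite.
* Ties and degenerate inputs: relRMSE on two constant curves and basis
  evaluation outside the domain are errors; zero-variance correlations are
  `NA` and counted; a rank-deficient sum-to-zero constraint is an error.
* Fit bundles are plain text: JSON manifest (17 significant digits — the
  exact round-trip width for doubles) plus `%.17g` arrays, so a reloaded
  fit reproduces predictions bit-identically.

## Testing worlds and their rationale

The acceptance suite fixes its simulation worlds a priori:

* *Surface and RMSE recovery*: 250 subjects split 80:20 (200 train),
  `sigma_eps` = 0.3, `sigma_b` = 0.1, REML. With subject curves present,
  the irreducible test RMSE floor for unseen subjects is
  $\sqrt{\sigma_\varepsilon^2 + \sigma_b^2} \approx 0.316$; the observed
  mean RMSE must sit within an estimation-error allowance of 0.15
  $\sigma_\varepsilon$ above that floor.
* *Scalar recovery*: `sigma_eps` = 0.1, `sigma_b` = 0.05, 200 subjects,
  fixed $\lambda = 1$ (unpenalized scalar coefficients are insensitive to
  the smoothing level; fixing it keeps the test fast and exactly
  reproducible).
* *Band calibration*: 200 replicates on one fixed 40-subject design with
  subject curves drawn on the model's own time basis and the ridge
  parameter at its oracle value $\sigma_\varepsilon^2/\sigma_{b,coef}^2$.
  This isolates the band construction itself; with the generator's
  default 6-dim subject basis the model is (mildly) misspecified and no
  fixed ridge parameter is exactly oracle, which is a statement about
  misspecification, not about the bands.

## Known limitations

* One smoothing parameter is shared across all subjects' random
  intercepts; subject-specific smoothness is not modelled.
* The gait cycle is treated as a non-cyclic domain; a cyclic basis would
  enforce continuity between t = 99 and t = 0.
* GCV recomputes the effective degrees of freedom per evaluation and is
  slow for cohort-scale designs; REML is the practical default there.
* No simultaneous confidence bands; no leave-one-subject-out
  cross-validation; no extrapolation beyond the training covariate range.
* Each outcome is fit independently; cross-outcome correlation is ignored
  both in fitting and in the generator.
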