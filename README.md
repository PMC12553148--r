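# gaitnorm

Normative walking biomechanics across the lifespan via penalized
function-on-scalar regression.

## What it is for

Assessing a movement impairment means comparing a patient's gait against
what a *comparable* healthy person would do — after controlling for sex,
age, anthropometry and walking characteristics. `gaitnorm` builds that
reference: it models sixteen lower-limb gait waveforms (joint angles in
deg, ground reaction forces in N/kg, joint moments in Nm/kg, joint powers
in W/kg, each time-normalised to 100 points of the gait cycle) as smooth
functions of seven scalar covariates — sex, age, walking speed, body mass,
height, cadence and side — and predicts the normative mean curve with
pointwise uncertainty for any covariate profile inside the training range.

## The model

For each outcome, the expectation of the trajectory `y_i(t)` is

```
y_i(t) = β0(t) + f_age(age_i, t) + f_speed(speed_i, t) + f_cad(cad_i, t)
       + f_ht(ht_i, t) + f_mass(mass_i, t)
       + β_sex·1[female_i] + β_side·1[right_i] + b_i(t) + ε_i(t)
```

where the `f(x, t)` are covariate-by-time surfaces (penalized B-spline
tensor products, sum-to-zero constrained), `b_i(t)` are smooth functional
random intercepts per subject, and `ε` is i.i.d. Gaussian. Fitting is
penalized least squares in sparse form with REML (or GCV) smoothing
selection; uncertainty comes from the Bayesian coefficient covariance.
Accuracy is scored on a participant-level 80:20 split with three
curve-level metrics: RMSE, relative RMSE (% of the mean curve range) and
Pearson correlation, aggregated as mean (SD) per outcome. A synthetic
lifespan cohort generator with known ground truth makes the whole pipeline
testable offline.

## Worked example

```r
library(gaitnorm)
tr  <- default_truth("knee_sagittal_angle", sigma_eps = 1.5, sigma_b = 2)
coh <- generate_cohort(n_subjects = 60, seed = 42, truth = tr)
sp  <- split_participants(unique(coh$covariates$subject_id), 0.8, seed = 1)
train <- coh$covariates$subject_id %in% sp$train_ids

fit <- fit_fosr(coh$curves[coh$curves$subject_id %in% sp$train_ids, ],
                coh$covariates[train, ],
                config = fosr_config(n_basis_t = 12, n_basis_x = 6,
                                     n_basis_tensor_t = 8))
evaluate_model(fit,
               coh$curves[!coh$curves$subject_id %in% sp$train_ids, ],
               coh$covariates[!train, ])
#> Evaluation of knee_sagittal_angle on 36 test curves
#>   RMSE    2.598 (0.929) deg
#>   relRMSE 4.89 (1.59) %
#>   cor     0.989 (0.006)

predict_band(fit, list(sex = "female", age = 34, speed = 1.25, mass = 62,
                       height = 1.68, cadence = 112, side = "left"),
             kind = "ci")
#> Predicted knee_sagittal_angle curve ( deg ) with ci band
#>   t     mean  lower95  upper95        sd
#> 1 0 13.91907 12.92729 14.91085 0.5060185
#> 2 1 14.99343 14.15747 15.82939 0.4265173
#> ...
```

The evaluation says: across the 36 held-out curves the predicted knee
flexion waveform deviates from the observed one by 2.6 deg on average
(RMSE), under 5% of the curve's range, with near-perfect shape agreement
(r = 0.99) — on synthetic data whose noise floor is 1.5 deg plus a 2 deg
subject effect that is unpredictable for unseen individuals. The
prediction table gives the normative mean and a pointwise 95% CI per gait
cycle percent; `kind = "sd"` instead returns a population-spread band for
plotting patient curves against. `extract_smooth_effect(fit, "age")`
returns the isolated age effect surface at the training age quartiles with
pointwise CIs.

## Command line

```sh
inst/cli/gaitnorm simulate --out data --seed 4
inst/cli/gaitnorm fit      --curves data/curves.csv --covariates data/covariates.csv \
                           --out fits --split-fraction 0.8 --split-seed 1
inst/cli/gaitnorm evaluate --curves data/curves.csv --covariates data/covariates.csv \
                           --fits fits --out report.csv
inst/cli/gaitnorm predict  --fit fits/fit_hip_sagittal_angle --sex female --age 30 \
                           --speed 1.2 --mass 60 --height 1.65 --cadence 110 \
                           --side left --out pred.csv
inst/cli/gaitnorm effects  --fit fits/fit_hip_sagittal_angle --covariate age --out eff.csv
```

Outputs are deterministic given the seed; logs (seed, config hash,
package version) go to stderr.

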