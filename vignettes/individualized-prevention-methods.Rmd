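---
title: "Methods: individualized preventive-intervention risk modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized preventive-intervention risk modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipirisk)
```

## The modeling problem

Among adults with prediabetes, intensive lifestyle intervention and
metformin both reduce 3-year diabetes risk relative to no intervention, but
not uniformly: the protective effect of lifestyle strengthens with age and
weakens with baseline fasting glucose, while metformin is relatively more
effective at higher BMI and glucose. A risk model that treats the
intervention as a predictor — and lets age, fasting plasma glucose (FPG),
and BMI interact with it — can predict each person's absolute 3-year risk
under every intervention scenario, not just the one they happened to
receive. `ipirisk` implements that model, the counterfactual and policy
analyses built on it, and the validation battery needed to trust it.

## The hazard model

The hazard for subject $i$ under arm $a \in \{\text{lifestyle},
\text{metformin}, \text{placebo}\}$ is

$$
h_i(t \mid a) = h_0(t)\,\exp\Big(
  \beta_{\text{hba1c}} z_{\text{hba1c},i} + \beta_{\text{trig}} z_{\text{trig},i}
  + \beta_{\text{sex}} \mathbf{1}\{\text{female}_i\}
  + \gamma_a + \beta_{\text{age},a} z_{\text{age},i}
  + \beta_{\text{fpg},a} z_{\text{fpg},i} + \beta_{\text{bmi},a} z_{\text{bmi},i}
\Big).
$$

Design choices worth making explicit:

* **Arm-specific ("conditional on treatment") coding.** Each interacted
  covariate gets one disjoint column per arm rather than a reference slope
  plus interaction contrasts. The two codings are exact linear
  reparameterizations; this one reports per-arm hazard ratios directly,
  which is how such models are read clinically. Arm main effects are two
  indicators against placebo.
* **Per-SD standardization.** Continuous predictors are centered at the
  fitting cohort's means and scaled by fixed constants (age 10.6 years, FPG
  6.7 mg/dL, BMI 6.6 kg/m²) so hazard ratios read per 1 SD in the population
  the constants describe; HbA1c and log-triglyceride scales default to the
  fitting cohort's SDs. A cohort-SD mode for all five is available through
  `model_spec()`. Rescaling a covariate's native units together with its
  constant leaves the fit unchanged (tested).
* **Triglycerides on the log scale.** The published summaries are
  median/IQR and strongly right-skewed; the model standardizes the natural
  log. This is a modeling choice, not something the source material
  prescribes.
* **Race/ethnicity is never a predictor.** It is carried in cohorts only
  for subgroup evaluation and fairness metrics.

### Estimation

`fit_cox()` maximizes the Cox partial likelihood by Newton–Raphson with
step-halving, from scratch. Efron tie handling is the default (more accurate
under heavy event-time ties, which exam-based ascertainment produces);
Breslow is selectable for compatibility with older software defaults.
Convergence requires max absolute score $< 10^{-8}$ or relative
log-likelihood change $< 10^{-10}$, within 50 iterations. The linear
predictor is shifted by its maximum before exponentiation (the partial
likelihood is shift-invariant), which guards against overflow. Degenerate
inputs have defined behavior: no events is an error; a singular information
matrix is an error naming the columns; coefficients diverging past $|\beta| >
15$ with a nondecreasing likelihood trigger a monotone-likelihood warning
per coefficient. Coefficient covariance is the inverse observed information;
CIs are Wald on the log scale. The test suite asserts agreement with
`survival::coxph` to $10^{-6}$ on random fixtures under both ties methods,
and score-test equivalence with the log-rank statistic.

Absolute risk uses the Breslow baseline cumulative hazard
$\hat H_0(t) = \sum_{t_j \le t} d_j / \sum_{k \in R(t_j)} e^{\hat\eta_k}$,
anchored at the centered covariate reference (cohort means, male, placebo),
and $\widehat{\text{risk}}(h) = 1 - \exp(-\hat H_0(h) e^{\hat\eta})$ at the
horizon $h$ (default 3 years). A horizon past the last observed time falls
back to the last baseline step with a warning.

## The synthetic-cohort generator

Because the source cohorts are controlled-access, all development and
testing runs on synthetic data whose generator is itself first-class,
tested code. It emulates:

* **Covariates** via a Gaussian copula: marginals are truncated normals
  (age 51 ± 11 y trial-like, 64 ± 10 y observational-like; BMI 34 ± 7 vs
  30 ± 6 kg/m²; FPG 106 ± 7 vs 101 ± 10 mg/dL; HbA1c 5.78 ± 0.40 vs
  5.75 ± 0.30%) and a lognormal for triglycerides matched to the published
  median/IQR. Truncation bounds are wide physiological guard rails (e.g.
  age 16–100), not eligibility windows, so sample moments reproduce the
  published ones within 1% at large n. Default correlations are 0.2 between
  FPG–HbA1c, FPG–BMI, and BMI–triglycerides and 0 elsewhere: the source
  populations publish only marginals, so the correlation matrix is an
  explicit free knob of the config.
* **Event times** by inverse-transform sampling,
  $T = -\log(U) / (h_0 e^{\text{lp}})$, under a constant baseline hazard. A
  Weibull option exists for robustness checks; over a 3-year horizon the
  baseline shape is secondary. Observed time is the minimum of event time,
  exponential dropout (default 0.02/year), and administrative censoring
  (default 3.2 years); neither censoring mechanism is published, so these
  are package defaults chosen to produce mild (~6–8%) pre-horizon censoring.
* **Arm effects by calibration.** The intercept scale and arm main effects
  are not published. `calibrate_generating_model()` solves them by
  univariate root-finding (`uniroot` on the closed-form marginal risk over a
  large Monte-Carlo covariate draw): first the baseline hazard to hit the
  marginal placebo 3-year risk (0.227, the sample-size-weighted mean of the
  published counterfactual placebo risks), then each arm's main effect to
  hit its marginal risk reduction (58% lifestyle, 31% metformin). With null
  covariate effects the placebo solution reduces to the exact closed form
  $h_0 = -\log(1 - 0.227)/3$. This calibration is the single largest
  reconstruction in the package and is deliberately prominent: the shipped
  generating model is simulation-derived, **not** the published risk
  equation.
* **Missingness** as MCAR per-column fractions on predictors only.

What the generator does *not* emulate — and hence what passing tests cannot
certify about real data: eligibility screening (the trial enrolls FPG 95–125
mg/dL; the generator draws the full normal range and only guards
physiological impossibility), interval-censored exam-based ascertainment
(onset is generated in continuous time), adherence and crossover,
informative missingness, and any covariate-dependent censoring.

## Imputation

Missing predictors are filled by aggregating each incomplete row's 5
nearest neighbours under Gower distance: the mean over pairwise-observed
variables of $|a-b|/\text{range}$ for continuous variables and 0/1 mismatch
for categorical ones. Aggregation is the mean for continuous variables and
the mode (ties toward the alphabetically lowest label) for categorical ones
— the aggregator is unstated in the source and fixed here by convention.
Ranges come from the cohort being imputed (or from a designated donor
cohort, e.g. the training fold during cross-validation); constant columns
leave the distance with a warning but are still imputable. Donors carry
only originally observed values (no chained imputation), equidistant donors
break by subject-id order, outcome columns and arm never enter the
distance, and a variable 100% missing is a hard error. Triangle inequality
is *not* asserted: Gower distance under missingness does not satisfy it.

## Counterfactuals, the optimal strategy, and policy NNT

`counterfactual_risks()` scores every subject under all three arms with
covariates held fixed — a pure covariate function, independent of the
observed arm. The optimal strategy is the argmin, with ties broken toward
lifestyle (the guideline first-line recommendation), then metformin. NNT
for a policy is $1/(\bar r_{\text{placebo}} - \bar r_{\text{policy}})$,
computed from mean *predicted* counterfactual risks rather than observed
events: that choice puts all three policies (including for
placebo-randomized and untreated observational subjects) on the same
footing, at the cost of inheriting any model miscalibration. Nonpositive
risk reductions yield an explicitly undefined NNT rather than an infinity.
By construction the model-guided policy's mean assigned risk is the
pointwise minimum, so its NNT can never exceed the single-arm policies' —
asserted, not assumed, in the tests.

One boundary phenomenon deserves its own paragraph. Under the
published-style interaction structure, the no-intervention scenario is
genuinely the argmin for subjects with FPG below roughly 91 mg/dL (about
0.07% of the generator's trial-like population): at very low glucose the
placebo FPG slope's steep gradient outruns the protective arm main effects.
Such subjects sit below the prediabetic range (FPG ≥ 95–100 mg/dL) and
would never be enrolled in the trial the model is built from, which is why
the published analysis can state that no intervention is never optimal. The
package asserts that property exactly on the prediabetic range and treats
the sub-range tail as out of the model's intended population; fitted models
on trial-sized cohorts can additionally misclassify a fraction of a percent
of subjects near the boundary through sampling noise in the slope
contrasts. The single-subject calculator warns on out-of-range inputs for
the same reason.

## Validation metrics

All binary classification metrics at the 3-year horizon must confront right
censoring. The default scheme is inverse-probability-of-censoring weighting
(IPCW): events by the horizon get weight $1/\hat G(T_i^-)$, subjects
followed to the horizon get $1/\hat G(h^-)$, and subjects censored before
the horizon get weight 0, where $\hat G$ is the Kaplan–Meier estimate of
the censoring distribution with events preceding censorings at ties. That
tie convention makes the weighted event prevalence equal $1 - \hat S_{KM}(h)$
exactly (tested on hand fixtures, including tied times). A simple-exclusion
scheme is available as a sensitivity fallback; the two coincide exactly
when nothing is censored before the horizon. Censoring exactly at the
horizon counts as event-free.

On top of the labels: the C-statistic is the weighted fraction of
case–noncase pairs ranked correctly (ties ½; exact against brute-force
enumeration on small fixtures; percentile bootstrap CI, 1000 resamples,
resampling subjects); calibration compares mean predicted risk with the
within-decile Kaplan–Meier observed risk and plain Greenwood intervals,
with quantile ties falling to the lower bin and unreachable horizons
evaluated at the last estimable time and flagged; net benefit is
$\text{TPR} - \text{FPR} \cdot \frac{p_t}{1-p_t}$ with rates per subject
screened, so $100\times$NB reads as true positives per 100 screened;
categorical NRI uses default cut-points (0.10, 0.20) aligned with the 20%
decision threshold used for net benefit and fairness (both configurable),
returns both reclassification matrices, and decomposes exactly into event
plus nonevent components; fairness reports per-group TPR/FPR at the
threshold with equal-opportunity and equalized-odds gaps as maximal
pairwise differences, excluding (and flagging) groups without cases; and
IPA is $1 - \text{Brier}/\text{Brier}_{\text{null}}$ against a
weighted-prevalence null.

Internal validation is stratified 10-fold cross-validation with the entire
pipeline — imputation included — refit inside each training fold;
held-out folds are imputed from training-fold donors only. Out-of-fold
predictions are pooled for one report, and the per-fold mean C-statistic is
reported alongside the pooled C (two defensible readings of a "mean
C-statistic"; both are provided). A fold without events triggers one
reshuffle, then an error. `compare_models()` runs the individualized and
main-effects-only variants through identical internal and external
validation and scores the individualized model against the standard with
the NRI.

## Numerical and reproducibility choices

Every stochastic routine takes an explicit seed and restores the caller's
RNG state; derived streams keep child seeds inside the 32-bit range.
Identical config + seed reproduces cohorts bit for bit, CSV artifacts byte
for byte, and reports identically. Model JSON serializes doubles at 17
significant digits so reloaded models reproduce in-memory predictions to
machine precision. Root-finding uses `uniroot` to tolerance $10^{-12}$ on
brackets wide enough for any plausible target; an unattainable target or
failed bracket is a diagnostic error, never a silent clamp.

## Problem sizes in the test suite

The suite exercises the study's own scale where the property demands it and
smaller sizes elsewhere: parameter recovery runs 100 replicate trials at
n = 2640 (the three-arm trial's analytic size), with recovery judged by
geometric-mean hazard ratios against 2 Monte-Carlo SEs and pooled 95%
Wald-CI coverage in [92%, 98%]; calibration fixed points and moment
recovery use n = 100 000; the well-specified decile-calibration and
fairness-exchangeability checks use n = 50 000–100 000; cross-validation
and comparison properties use n = 1 200–4 000, sizes at which fold-level
fits remain well conditioned. These were chosen as the smallest sizes at
which the Monte-Carlo error of each check is comfortably below its
assertion margin.

## Known limitations

* The shipped default model is simulation-derived; its coefficients mimic
  the published per-SD structure but are not the published scoring
  constants, and nothing here substitutes for access to the source data.
* MCAR is the only missingness mechanism generated, so imputation quality
  under MAR/MNAR is untested.
* Continuous-time ascertainment overstates the precision of exam-interval
  diagnosis; metrics at the 3-year horizon inherit that idealization.
* The observational-like population is scored with placebo coefficients —
  "no intervention" is assumed exchangeable with randomized placebo
  conditional on the predictors.
* NNT from predicted (not observed) risks is a modeling convention; under
  miscalibration the policy NNTs shift together but their ordering is
  structural.
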