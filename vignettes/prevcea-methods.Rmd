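---
title: "Methods: trial-based cost-effectiveness analysis in prevcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis in prevcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`prevcea` evaluates the cost-effectiveness of two prevention strategies —
a multidomain lifestyle intervention (MI) and omega-3 polyunsaturated fatty
acid supplementation (PFA) — alone and combined, against placebo, in a
four-arm randomized trial of community-dwelling adults aged 70+ followed
for three years. This vignette documents the models, their assumptions, the
tunable parameters, and the design decisions that were genuinely open.

## The generative model behind the synthetic trial

Every stage of the package is testable because the trial generator owns the
ground truth.

**Design.** Four equal-allocation arms (`PFA+MI`, `PFA`, `MI`, `placebo`),
default 380 participants per arm recruited across 13 centers. Baseline
covariates follow the profile of this trial population: age from a normal
distribution (mean 75.4 y, SD 4.4 y) left-truncated at the 70-year
eligibility floor; 36% male; frailty categories robust / pre-frail / frail
at 56 / 41 / 3%; four education levels; and a medical-history condition
count drawn Binomial(16, 0.4), which puts the empirical terciles near 5 and
8 conditions, matching the tercile cut points used by multivariable cost
models in this setting.

**Cognition.** Four raw test scores (free-and-cued selective reminding
recall, MMSE orientation items, digit symbol substitution, category
fluency) are generated at visits 0, 6, 12, 24 and 36 months as

  raw = test mean + test SD × (latent + ε),

where the shared latent cognition combines a participant intercept
(SD 0.45), a center intercept (SD 0.05) and the mean trajectory, and ε is a
per-test residual (SD 0.65). The composite Z score downstream standardizes
each test to the *baseline cohort* mean/SD and averages the four; because
all four tests share the same latent structure, a mean shift of δ×s on the
latent scale (s the baseline SD of latent + residual) moves the composite
by δ Z points. Arm effects ramp linearly in time and are scaled this way so
that the expected 36-month composite-Z contrast versus placebo equals the
configured `true_z_effects` — default 0.093 (PFA+MI), 0.079 (MI), 0.011
(PFA), the between-group differences reported for this trial family. The
placebo trajectory declines by 0.18 Z points over 36 months. The residual
SD was calibrated so that the 36-month change score has an SD near 0.6,
which makes the mixed-model contrast standard error at 380/arm about
0.045 — matching the reported confidence interval half-widths (≈0.09) for
these contrasts. The visit grid is configurable; 0/6/12/24/36 months is the
design reference, while costs are collected over six 6-month windows.

**Resource use and costs.** Each participant × 6-month period × subcategory
generates a Poisson number of events. The default component specification
(`default_cost_components()`) is calibrated so the *placebo-arm* expected
3-year component costs match the published payer-perspective means for this
population — inpatient ≈ €3,829, consultations ≈ €495, paramedical ≈ €393,
medical procedures ≈ €228, transportation ≈ €15, medication ≈ €2,137, total
≈ €7,106 — split uniformly across periods. Event rates in the three
intervention arms are scaled by multipliers 1.084 / 1.119 / 1.104
(PFA+MI / PFA / MI), the ratios of the published per-arm totals-without-
intervention to the placebo total, so that synthetic cost increments land
at the scale of the published ones. Components deliberately exercise all
four valuation rules (fixed tariff, per diem, DDD drug pricing,
gamma-sampled), and the gamma components are right-skewed (inpatient
coefficient of variation 1.5).

**Missingness.** Economic data are missing at the level of the 3-year
cumulative total for ≈13.5% of participants per arm (the observed 12–15%
band), and 15% miss the final cognitive visit (monotone dropout). Both
mechanisms are logistic in *observed* covariates only — age tercile and
frailty — with the intercept solved numerically so the expected rate equals
the target: missing at random by construction. A `mnar_shift` argument adds
a dependence on a latent cost proxy for sensitivity experiments on the
attrition diagnostic. The untouched dataset is retained in `$complete` so
tests can compare against the oracle.

**What the generator does not emulate.** Eligibility screening, recruitment
dynamics, adherence, per-period cost autocorrelation within participants
(periods are conditionally independent given the arm rate), correlation
between cognition and healthcare costs, and seasonal or center-level cost
variation. Passing tests therefore demonstrate that the *statistical
machinery* is correct under a faithful but simplified data-generating
process; they do not validate the clinical or economic conclusions on real
trial data, where confounding between cognition and cost trajectories and
non-ignorable dropout are live concerns.

## Costing

All values are 2018 euros from the payer perspective; no discounting is
applied over the 3-year horizon. Interventions are priced from their
published unit costs: PFA at €0.50 per capsule × 365.5 capsules/year ×
3 years = €548.25 (≈ the printed €549; the printed figure appears to round
up, and we follow the formula); MI at a €40 mean hourly wage × 2.30-hour
sessions × the number of priced sessions. `mi_sessions_priced` defaults to
**10**: the published schedule (twice weekly in month 1, weekly in month 2,
monthly thereafter) implies roughly 46 sessions, yet the published mean MI
cost (€920) equals exactly 10 × €92 — consistent with group sessions being
cost-shared across participants. The default reproduces the published
pricing; the schedule-derived count is one argument away.

Costs are kept at full precision internally; report tables round half-up to
whole euros. The additive identity *total-with = total-without +
intervention* holds exactly per participant, as does scale equivariance
(doubling every tariff doubles every cost).

## Descriptives

Complete cases are participants with observed economic data *and* an
observed final visit — "complete follow-up" made operational. Mean 3-year
costs per component and arm carry BCa bootstrap 95% intervals
(B = 2,000 by default; bias-correction z₀ from the bootstrap distribution
of the mean, acceleration from the jackknife skewness), with a degenerate
flag (interval collapsed, a = 0) for constant samples. Group comparisons
use the tie-corrected Kruskal–Wallis test via `stats::kruskal.test`;
baseline categorical covariates use chi-square. Both the frequency and the
cost columns are emitted, since either can be of interest.

## Imputation

Missing 3-year cumulative totals (not per-period costs — missingness is
generated, and published, at the cumulative level) are imputed by
predictive mean matching with m = 20 imputations and k = 5 donors, type-1
matching: donors keep least-squares predictions, each imputation draws the
coefficients and residual variance from their approximate posterior, and
every missing case receives the *observed* outcome of a uniformly drawn
nearest-prediction donor, so imputed values never leave the observed
support. Predictors are the published imputation set: age tercile, gender,
arm, frailty, medical-history tercile (terciles computed on the observed
marginal distribution, ties to the lower tercile). Estimates are pooled by
Rubin's rules with Barnard–Rubin degrees of freedom. m and k are not stated
for the original analysis; 20 and 5 are conventional defaults at this
missingness rate.

The attrition diagnostic is a Hausman-type quadratic form comparing the
complete-case and imputation-based estimators of the same parameter vector,
with the variance difference inverted by Moore–Penrose when not positive
definite (flagged). The exact construction used originally is unstated;
this generalized form is one defensible reading, and its null calibration
and MNAR power are verified by simulation in the test suite.

## Adjustment

Costs: gamma GLM with log link (`stats::glm`), covariates = imputation
predictors plus baseline-Z terciles; exponentiated coefficients are
relative cost risks with Wald intervals. The adjusted per-arm mean uses
**marginal standardization** (every participant predicted under every arm,
then averaged) rather than the model's own fitted values; both modes are
available, and the default was chosen because recycled predictions answer
the population-level "what if everyone received arm j" question that the
increment ΔC represents. Delta-method variances feed Rubin pooling.
Non-positive totals (possible in synthetic data, implausible in the real
registry) error by default; an explicit `zero_adjust` option offsets by
half the smallest positive cost. Note one consequence of the nonlinear
link: the exact decomposition ΔC(with) − ΔC(without) = intervention-cost
difference holds exactly for raw or fitted arm means, but only
approximately after marginal standardization.

Effectiveness: linear mixed model `z ~ arm * visit + (1|center) + (1|id)`
fitted by maximum likelihood (ML rather than REML, so nested fixed-effect
structures remain likelihood-comparable), time categorical. The 36-month
contrast is the arm × final-visit interaction — the arm difference in
change from baseline, which is invariant to adding a constant to all Z
scores. A singular center variance component triggers a flagged refit
without the center intercept.

## The cost-effectiveness core

ICER quadrants follow cost-effectiveness-plane conventions: NE ratios are
meaningful; dominant (cheaper, more effective) and dominated arms report no
ratio interpretation; SW ratios carry a caution flag; ΔE = 0 flags the
ratio undefined rather than erroring. The bootstrap resamples participants
with replacement *within arms* — the design is randomized by arm, and
stratification preserves it (the original report does not state
stratification; unstratified resampling is a one-line change). The default
per-replicate recomputation is the fast arm-mean difference; refitting the
cost GLM per replicate is available (`mode = "adjusted"`). With multiply
imputed costs, replicates cycle through the m completed datasets so
between-imputation variability widens the cloud. Ellipses use the replicate
mean and covariance with χ²₂ radius (5.9915 at 95%). The CEAC is computed
on the net-benefit scale, `P(λ·ΔE − ΔC > 0)`, which stays well defined when
replicates cross quadrants — ICER ratios are never averaged. The WTP grid
defaults to €0–150,000 in €500 steps, spanning three times the €50,000
headline threshold.

The binary effectiveness unit counts a participant as "no aggravation" when
the Z change is *strictly greater* than −0.3 points (a 0.3-point decrease
is the minimum clinically significant decline, so a change of exactly −0.3
counts as aggravation; the cutoff and strictness are arguments).

## Numerical choices and problem sizes

Seeds: every user-facing function takes one; internal stages derive
distinct streams from the master seed via a fixed linear map kept inside
32-bit range. GLM convergence follows `stats::glm` defaults (IRLS,
tolerance 1e-8); the saturated arm-only gamma model reproduces observed arm
means to that tolerance, which the tests assert. Degenerate inputs
(constant samples, singular replicate covariance, empty event lists, zero
baseline SD) return flagged results or named errors rather than NaNs.

The test suite sizes its simulations to be informative yet quick: BCa
coverage for an exponential mean uses 2,000 outer replications at n = 50
with B = 999; the Kruskal–Wallis type-I rate uses 2,000 null trials of
4 × 100; gamma-GLM interval coverage uses 500 fits at n = 1,500; the
mixed-model recovery and the qualitative cost-effectiveness check run at
the trial's own scale, 380 per arm, with B = 400–1,000 bootstrap
replicates. These sizes give Monte-Carlo standard errors a factor of
several below the tolerance each assertion uses.

## Known limitations

No QALY estimation (deliberately: generic utility instruments are
insensitive in this population, and the original evaluation used the
cognitive Z score); no indirect or informal-care costs; no discounting; no
lifetime extrapolation — this is a within-trial analysis. The Hausman-type
attrition check and the PMM settings are defensible readings of
under-specified methods, not reconstructions. Real tariff nomenclatures
(DRG, CCAM, NABM) are abstracted into the tariff table; the package prices
whatever rules that table declares and makes no attempt to encode national
fee schedules.
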