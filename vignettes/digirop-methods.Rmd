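---
title: "Models and methods behind the digirop decision-support tool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the digirop decision-support tool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Retinopathy of prematurity (ROP) screening examines essentially every very
preterm infant many times, yet only about one in twenty ever needs
treatment. The DIGIROP 2.0 approach replaces blanket screening schedules
with individual risk estimates: a *prescreen* model available from
postnatal day 14 (once the 14-day parenteral nutrition category is known),
and a *screen* model updated weekly from postnatal weeks 6 to 14 as eye
examinations accrue. Probability cutoffs calibrated to 100% training
sensitivity turn the risk estimates into a discharge decision-support
tool. This vignette explains the models, the synthetic cohort generator
used to exercise them, the numerical choices, and what the accompanying
tests do and do not establish.

## The prescreen hazard model

Treatment risk is modeled through a time-to-treatment hazard over the
first 20 postnatal weeks,

$$\lambda(t \mid x) = \exp\{f(t) + x'\beta\},$$

with a restricted cubic spline baseline log-hazard $f(t)$ and covariates:
gestational age (GA, weeks, centered at 28.5), sex (girl as reference),
birth weight (per 100 g, centered at 1172 g), and the three-level
parenteral nutrition duration (PND) category — under 14 days (reference),
14 days or more, unknown. Unknown PND is a modeled level, never imputed.
Candidate interactions (sex x PND, GA x PND) are fitted exhaustively and
the model with the smallest AIC is kept.

Fitting uses the classical device of splitting follow-up into person-time
intervals and maximizing a Poisson likelihood with a log-exposure offset
(`split_person_time()`, `fit_prescreen()`). Two refinements make the fit
essentially independent of the split granularity:

* each treatment event is isolated in a narrow terminal interval (0.1
  weeks), so the event term tracks the hazard at the event time rather
  than an interval average;
* after an initial midpoint fit, each interval's spline-basis row is
  replaced by its hazard-weighted average $\bar B = \int B e^{f} / \int
  e^{f}$ and the offset by $\log \int e^{f} - \bar B'\hat\theta$
  (five-node Simpson per unique interval), iterating with damped updates.
  At the fixed point the estimating equations coincide with the
  continuous-time score, so one-week and 2.5-week splits give the same
  estimates to well within sampling noise.

The per-infant risk is $p = 1 - \exp\{-H(20)\}$ with $H(t) = \int_0^t
\lambda$ computed by composite Simpson quadrature refined to a relative
tolerance of $10^{-8}$ (`cumulative_hazard()`, `predict()`); the
log-odds of $p$ is the carrier of prescreen information into the weekly
models. The default baseline uses four internal knots at event-time
quantiles (0.2, 0.4, 0.6, 0.8) with boundary knots at the 1st and 99th
event-time percentiles; the published model's exact basis is not public,
so the spline family here is a documented stand-in with the same role.

Where follow-up of non-treated infants ends is likewise not stated; the
package censors at a fixed 20-week horizon (the span over which the
hazard is integrated) unless a per-infant `last_exam_pna_weeks` says
otherwise. This is flagged as an assumption, not a registry fact.

## The weekly screen models

For each postnatal week $w = 6, \dots, 14$, a logistic regression of
eventual treatment is fitted on infants still under screening at week
$w$ (`build_screen_observations()`, `fit_screen()`): predictors are the
prescreen log-odds, an indicator of ROP detected by week $w$ (first
diagnosis at or before $w$ — the boundary is closed at the examination
week), the time since first detection $(w - t_{dx})$, and (AIC-selected)
a detection-by-log-odds interaction. Infants treated before week $w$ are
excluded — their outcome is already realized. The published coding of the
age-at-first-detection term is in unavailable supplementary material; the
"time since detection with a main detection indicator" coding used here
is a documented choice.

Separation (a covariate level with all or no events) in any logistic or
Poisson fit triggers a small ridge-penalized IRLS fallback with a
warning; the penalty (lambda = 1e-3, intercept unpenalized) is written
in-package because no penalized-likelihood fallback is otherwise
available to depend on.

## Cutoff calibration and the decision tool

For each GA stratum (completed weeks <=24, 25, ..., 30, >=31) and each
stage (prescreen, week 6, ..., week 14), the discharge cutoff is the
minimum risk among treated infants scored at that stratum and stage
minus a safety margin epsilon = 1e-6 (`calibrate_cutoffs()`). The margin
exists only to make ties at the minimum keep the treated infant; strata
with no treated infants inherit the pooled minimum, and a stage with no
scored treated infants discharges nobody. By construction the tool's
training sensitivity is exactly 1. Whether the published tool pools
sparse GA strata is unstated; the pooled-minimum fallback is this
package's choice.

The sequential policy (`apply_tool()`) scores every infant at the
prescreen stage (decision day 14) and then weekly; an infant is
discharged at the first stage with risk strictly below its stratum
cutoff, and an infant already treated carries no later scores, so it can
never be discharged after treatment. On held-out data a discharge
followed by later treatment is exactly a sensitivity failure — the
future outcome is never consulted. Infants with detected ROP remain
dischargeable by default (the screen model prices detection in); a flag
forbids it for conservative deployments.

`tool_metrics()` reports sensitivity and *cumulative specificity*: among
never-treated infants, the fraction released at or before each stage,
nondecreasing by construction.

## The synthetic cohort generator

Registry data are not public, so `simulate_cohort()` draws cohorts whose
margins emulate the published cohort structure: GA truncated-normal
(mean 28.5, SD 2.4, range 21.9-39.4 weeks), 45.5% girls, birth weight
conditional-normal on GA (slope 140 g/week, residual SD 186 g, marginal
mean/SD about 1172/384 g), PND category probability declining with GA
(about 24% of known-PND infants at >=14 days, mean GA near 26 weeks in
that group), 14.4% unknown PND, any-ROP incidence near 28.5% with
log-normal onset (median 8.4 weeks), and treatment near 5.4% with
conditional median near 12.6 weeks. The intercept-like constants
(`pnd_a = -1.85`, `rop_a = -1.92`, `baseline_level = -6.257`) were
calibrated once, by bisection against these target margins at n =
150 000, and frozen.

Treatment event times are generated by inverting the cumulative hazard
of exactly the spline family the estimator fits, with the *observed*
PND category (including "unknown") driving the hazard — masking happens
before outcomes are drawn and is independent of them by default (a
switch makes it outcome-dependent for robustness experiments). This
makes parameter recovery well-posed: the recovery test at n = 50 000
requires every coefficient within three standard errors of the
generating truth. Daily weight series for the G-ROP comparator ramp from
5 to 25 g/day with optional measurement noise and a configurable
missing-series fraction (default 9%).

What the generator does *not* emulate: multiple births and center
effects, secular trends, the Swedish growth reference behind true birth
weight SD scores (standardized weights are emitted directly), informative
censoring, and real examination schedules. Passing tests on these
cohorts therefore demonstrate internal correctness of the estimators and
the calibration logic — not clinical performance on real infants, which
the published registry study addresses.

## Statistical primitives

The package implements the analysis statistics it needs as pure
functions: Woolf log-scale odds-ratio intervals (chosen because they
reproduce the published crude intervals from the cohort margins),
covariate-adjusted logistic odds ratios via `glm`, Miettinen-Nurminen
score limits for risk differences (constrained MLE by the closed-form
cubic; limits by bisection to 1e-8, matched in tests against an
independent grid-inversion oracle), Clopper-Pearson exact intervals
(Beta quantiles; for $x = n$ the lower bound is $(\alpha/2)^{1/n}$,
which reproduces the published 99.2 and 97.6 lower bounds), rank/
trapezoidal AUC with midrank ties, Youden-index cutoff search over
candidate parenteral-nutrition cutoffs of 7-28 days with ties broken
toward the smaller cutoff, the Hosmer-Lemeshow test (deciles of risk,
g - 2 degrees of freedom, neighbor-merging on ties), the exact
two-sided sign test (twice the smaller binomial tail at p = 1/2, capped
at one — identical to the symmetric-null minimum-likelihood convention),
and Spearman correlation as Pearson on midranks. All tests are
two-sided at the 0.05 level with no multiplicity adjustment, matching
the analysis conventions of the study design.

## Evaluation harness

`cross_validate()` runs the entire pipeline (prescreen fit, screen fit,
cutoff calibration) inside each of k = 10 folds, stratified on treatment
outcome and GA stratum — whether the published cross-validation was
stratified is unstated, so stratification is a documented default with
the seed logged. `temporal_validate()` refits nothing on the validation
side. Comparisons with rule-based screening go through the G-ROP engine:
linear interpolation for window-endpoint weights, strictly-below
threshold semantics (at-threshold gains do not fire; the published text
does not resolve this boundary, so it ships as the default of an
editable rule configuration), and the convention that any missing datum
resolves to "screen". Superiority is lexicographic: failing 100%
sensitivity loses outright; otherwise the exact sign test on discordant
discharge decisions among never-treated infants decides.

## Problem sizes and numerical notes

The test-suite defaults work at cohort sizes of a few thousand infants
(shared fixtures at n = 4000), with the parameter-recovery check at
n = 50 000 and the calibration-sensitivity property over 1000 cohorts of
n = 500; the acceptance script runs the pipeline at the study's cohort
sizes (8814 development, 2325 validation, a 249-infant comparator
subset). These sizes were chosen so each property is tested at the scale
that makes it informative. Degenerate inputs are handled explicitly:
zero-cell 2x2 tables error unless the Haldane-Anscombe correction is
requested, constant predictions collapse the calibration and
Hosmer-Lemeshow groupings to a single bin, a screen week with a single
outcome class is a hard error, and empty cohorts are fatal everywhere
calibration is involved.

## Known limitations

* The published model coefficients, basis and cutoff values (supplementary
  tables) are not public; this package reproduces the *method*, and its
  printed-number checks are limited to statistics derivable from the
  published cohort margins.
* The min-minus-epsilon cutoff rule is deliberately fragile on held-out
  data — one unusually low-risk treated infant moves a stratum cutoff to
  zero. That is the price of exact 100% training sensitivity and is
  visible in the cross-validation sensitivities below 1.
* The ridge fallback after separation gives finite but mildly shrunken
  coefficients; its intervals are approximate.
* WINROP is not reimplemented (the algorithm is proprietary); external
  decision vectors can be supplied to the comparison harness instead.
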