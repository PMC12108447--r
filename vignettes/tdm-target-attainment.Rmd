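---
title: "Beta-lactam TDM target attainment: models, rules and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-lactam TDM target attainment: models, rules and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdmattain)
```

`tdmattain` implements a beta-lactam therapeutic drug monitoring (TDM)
analysis pipeline for critically ill patients: individual pharmacokinetic
reconstruction from routine peak/trough samples, free-drug PK/PD target
attainment, MIC resolution rules, therapy-adjustment coding and
recommendation, outcome regressions and a time-to-discharge analysis — all
exercised against a calibrated synthetic ICU cohort generator so that every
stage is testable without patient data. This vignette documents the models,
the conventions where the science leaves choices open, and what the
synthetic cohort does and does not establish.

## The pharmacokinetic model

Each TDM occasion is modelled as a one-compartment system with first-order
elimination and zero-order (constant-rate) infusion, at steady state. The
steady-state assumption reflects practice: the first sample is typically
drawn 2–3 days into therapy, several half-lives for these drugs, so
accumulation from the first dose is not modelled.

From a peak concentration $C_p$ drawn at time $t_p$ after the start of the
infusion (after its end) and a trough $C_t$ at $t_t \le \tau$ in the same
interval,

$$k_e = \frac{\ln(C_p/C_t)}{t_t - t_p}, \qquad t_{1/2} = \ln 2 / k_e.$$

The end-of-infusion maximum is back-extrapolated,
$C_{max,ss} = C_p e^{k_e (t_p - T_{inf})}$, the interval-end minimum is the
trough extrapolated forward to $\tau$ if drawn earlier, and clearance
follows from the steady-state infusion equation

$$CL = \frac{D\,(1 - e^{-k_e T_{inf}})}{T_{inf}\, C_{max,ss}\,
      (1 - e^{-k_e \tau})}, \qquad V = CL/k_e.$$

Within one steady-state interval the free-concentration profile is
piecewise monotone: a rising exponential toward an asymptote during the
infusion (the exact steady-state superposition, not an assumption that the
infusion phase sits above the MIC) and a falling exponential afterwards.
Each phase therefore crosses a threshold at most once and the crossing
times have closed forms, giving fT>threshold without numerical
integration. The closed form is verified in the test suite against a
0.001 h grid over the interval (agreement within 0.5 percentage points on
1,000 random scenarios) and the reconstruction against a multi-dose
superposition oracle.

Total concentrations are converted to free with fixed published unbound
fractions (ampicillin and cefepime 80% free, aztreonam 44%, cefazolin 20%,
ceftriaxone 10%, meropenem 98%, oxacillin 5%, piperacillin 70%). Drugs
without a configured binding value are a hard configuration error — there
is no silent default.

Conventions worth stating:

* **Thresholds are strict** (`free concentration > h × MIC`). A free trough
  exactly equal to the MIC is boundary contact of measure zero and counts
  as attained for intermittent profiles; for the flat continuous-infusion
  profile the step is strict, so free Css exactly at a threshold does *not*
  attain it.
* **Units are fixed**: hours, mg, L, mg/L, with days only for days-to-TDM
  and length of stay. No unit inference is attempted.
* **One peak/trough pair per occasion**: the earliest peak and the first
  trough after it. Trough-only occasions are rejected with a status
  message, never silently dropped or imputed.
* Continuous infusions use the arithmetic mean of one or two random samples
  as the plateau; attainment is then a step function and fCmin/MIC equals
  free Css over MIC.

## MIC resolution

The effective MIC for an episode follows a fixed hierarchy: the highest
measured MIC across all isolates of the episode (polymicrobial rule);
a fixed 2 mg/L target for cefazolin against methicillin-susceptible
*S. aureus*, which overrides a measured value (this override is
configurable); otherwise the breakpoint of the suspected causative
pathogen. The bundled breakpoint table is a small synthetic CLSI-style
fixture — replace it for real analyses. Drug–organism pairs absent from
the table (including intrinsic resistance) resolve to an error rather than
an arbitrary high MIC, matching a study population from which resistant
infections were excluded. Every resolution carries a provenance label
(`measured_max`, `mssa_cefazolin_rule`, `breakpoint`), so the fraction of
breakpoint-based occasions is always reportable.

## Therapy adjustment

A change in therapy is coded on the ordinal scale −1/0/+1 from three
components: total daily dose, dosing frequency and infusion duration. Any
component strictly up with none down is an increase; the mirror case a
decrease. Components moving in opposite directions are not defined by the
coding; they are resolved by comparing predicted attainment of the two
regimens at the episode's MIC and target — exposure being the axis the
definitions track — with the predicted free trough breaking fT ties
(commonly both profiles sit at 100%). This keeps the classification
antisymmetric.

`recommend_regimen()` predicts steady-state attainment for every candidate
in a per-drug dose menu from the reconstructed CL and V (linear kinetics)
and returns the candidate with the lowest total daily dose — then fewest
administrations, then shortest infusion — achieving 100% fT above the
chosen multiple of the MIC. If nothing attains, the maximal-attainment
candidate is returned flagged `best_effort`, with ties broken toward the
highest predicted free trough so that a hopeless target yields the most
aggressive reasonable regimen rather than an arbitrary cheap one. The
menus reflect label-style adult dosing and are configuration, not clinical
advice; renal dose caps are not modelled (the generator encodes renal
failure through clearance instead).

The PK/PD target itself, 100% fT above 1–4 × MIC, is a clinician's choice
in practice; it is an explicit `target_multiplier` parameter, default 1.

## The synthetic cohort generator

`generate_cohort()` produces episode-level data with the statistical
structure the downstream analyses assume. Defaults encode the study
conditions the package is calibrated to: 297 infection episodes from 268
ICU patients (29 second infections on random patients, treated as
independent); age 56 (SD 17) years, weight 82 (32) kg truncated above
30 kg, 57% male, 14% on renal replacement therapy, SOFA 6 (4), baseline
creatinine 1.26 (1.14) mg/dL truncated above 0.2; a lung-dominant source
mix (44% lung, 17% bacteremia, 7% intra-abdominal, ...); a
cefepime-dominant drug mix; 91% intermittent infusions; and a log-normal
days-to-first-TDM distribution fitted by least squares in log-quantile
space to a median of 2.7 d with IQR 1.7–4.7 (the IQR is asymmetric around
the median, hence the fit; it gives sdlog ≈ 0.75).

Mild covariate correlation beyond the model terms is induced by one shared
severity latent variable loading 0.3 on SOFA and RRT; no joint distribution
is claimed beyond that.

True kinetics scale a per-drug typical clearance with creatinine clearance
(Cockcroft–Gault, exponent 0.75), replace it with a fixed reduced value on
RRT, and scale volume with weight, each with log-normal between-patient
variability (sdlog 0.40 and 0.20). The typical values are ICU-like —
clearance reduced and volume expanded relative to healthy volunteers — so
that half-lives and trough/MIC ratios resemble septic patients. Samples
are forward-simulated from the true profile at the nominal draw times
(peak 1 h after the end of the infusion, trough at the end of the
interval) with 10% multiplicative log-normal noise. Setting the
variability and noise parameters to zero reproduces the true parameters
exactly through the estimation path, which the tests exploit.

Change groups are not assigned; they *emerge* from running the adjustment
rules on each episode's reconstructed attainment, with two stochastic
clinician elements: the target multiplier (1–4, drifting upward with
SOFA) and a de-escalation probability (0.48) applied when the current
regimen already attains — escalation on failure is always acted on,
de-escalation of a working regimen only sometimes, as in practice. The
handful of episodes whose peak/trough pair is uninformative (noise
reversing the decline on slow-elimination patients, about 1%) stay in the
no-change group, mirroring a clinician without usable results. Under the
defaults this yields roughly 57% changed therapy, split ≈ 31% decrease /
25% increase, and the PK/MIC/behaviour defaults were calibrated once,
jointly, to those cohort-level fractions.

Outcomes are then drawn from explicit models whose true effects are the
adjusted odds ratios the analyses should recover:

* clinical cure: logit⁻¹(α_c + ln(0.92)·days-to-TDM + ln(1.17)·increase +
  ln(1.25)·decrease);
* 30-day mortality: logit⁻¹(α_m + ln(1.14)·SOFA + ln(2.07)·RRT +
  ln(1.05)·age + ln(4.82)·intra-abdominal + ln(0.36)·increase +
  ln(0.67)·decrease);
* hospital length of stay, survivors only: log-normal (sdlog 0.85) with
  group medians ordered increase (18 d) < no change (22 d) < decrease
  (27 d), administratively censored past 50 days.

Regimen change enters as categorical contrasts against the no-change
reference rather than a single ordinal slope: the three pairwise contrasts
the models must reproduce are not consistent with one ordinal coefficient,
so categorical coding with a derived increase-vs-decrease contrast is the
faithful parameterisation. Mortality is a 30-day binary, not a hazard, and
length of stay exists only for survivors, which is exactly the population
the time-to-discharge analysis uses.

Intercepts α_c and α_m are free calibration constants. When left `NULL`
they are root-solved on the cohort's own linear predictors so the expected
marginal proportions equal the targets (75% cure, 20% mortality) exactly;
`calibrate_intercepts()` exposes the same root-finding over a large
Monte-Carlo cohort. With all coefficients zero the solution reduces to the
closed-form logit of the target, which the tests assert.

**What passing tests show — and don't.** Parameter recovery on this
generator demonstrates that the estimation pipeline is consistent for data
of this structure: correctly specified logistic models, independent
episodes, no informative censoring, no unmeasured confounding beyond the
modelled terms, MAR-free complete data. Real TDM cohorts guarantee none of
that: the generator does not emulate assay error structure, concentrations
below the quantification limit, within-patient correlation of repeated
episodes, drug switches, or confounding by indication in the
adjust-vs-not decision beyond the modelled severity link. Agreement on
synthetic data is a necessary check of the software and the estimators,
not evidence about any particular hospital's patients.

## Statistical stage

Logistic models are fitted by full Newton iteration (IRLS) to a gradient
tolerance of 1e−8, at most 100 iterations, with Wald standard errors from
the observed information, `exp(β ± 1.96·SE)` intervals and two-sided Wald
p-values — the reporting conventions of the tables the pipeline mirrors.
Singular designs name the offending columns; separation is surfaced as an
explicit error (detected by degenerate Wald SEs), never a silent estimate.
The fitter is cross-checked against `stats::glm` to 1e−6 and against the
closed-form 2×2 cross-product odds ratio.

The time-to-discharge analysis excludes 30-day deaths, censors stays
beyond 50 days, and uses the Kaplan–Meier product-limit estimator and the
standard log-rank test (aggregated-increment tie handling), both via the
survival package; the tests check the product-limit arithmetic by hand and
the log-rank p-value against a 10,000-draw permutation reference.
Episodes, not patients, are the analysis unit, and no clustering
correction is applied. Two-sided 0.05 is the significance convention.

## Problem sizes

The packaged checks use one cohort of 50,000 episodes for parameter
recovery (every adjusted OR within two Wald SEs of its generating value),
200 cohorts of 297 episodes for the calibration marginals, 1,000 random
scenarios for the PK closed-form/grid equivalence, and permutation
references at n ≤ 100. These sizes put Monte-Carlo error well inside the
tolerances while keeping a full run in tens of seconds.

## Known limitations

Single-compartment, linear kinetics only; no Bayesian or population-PK
borrowing across patients; no assay-error or LOQ modelling; no renal dose
caps or RRT-specific menus; no drug switching or combination therapy; no
upper exposure (toxicity) bound, because none is defined for the
recommendation target; survival beyond hospital discharge is out of scope.
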