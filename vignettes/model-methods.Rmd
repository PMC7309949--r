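---
title: "Methods: the TAI versus SBC cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the TAI versus SBC cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbdcea)
```

`nbdcea` models the cost-effectiveness of transanal irrigation (TAI) against
standard bowel care (SBC) for neurogenic bowel dysfunction (NBD) after spinal
cord injury, in a Japanese health-care setting.  This vignette is the
package's account of the model: its structure and assumptions, the
parameters that matter, the numerical conventions, and what the synthetic
data used in testing can and cannot show.

## The cohort model

Six health states: TAI responder, TAI non-responder, resumed SBC, SBC,
stoma, and dead.  The TAI arm enters split 60/40 between responders and
non-responders; the SBC arm enters entirely in standard care.  Responders
are assumed to retain satisfactory bowel management for life and never
undergo colostomy.  Non-responders withdraw from irrigation with probability
0.60 per half-year cycle and resume standard care, where they face the same
0.033%-per-cycle stoma construction rate as the SBC arm.  The stoma state is
absorbing apart from death.

Cycles are six months long, matching the time a patient must spend failing
conservative care to be assessed for irrigation; the horizon is lifetime,
realised as simulation until the cohort reaches age 110.  Costs are yen from
the payer perspective in the base case; QALYs are the effectiveness measure;
both are discounted at 2% per year.

Two structural choices deserve emphasis because the underlying evidence
leaves them open:

* **Withdrawal dynamics.**  The published 60% figure can be read either as a
  per-cycle withdrawal probability or as all non-responders leaving after
  the first cycle.  The per-cycle reading is the default
  (`settings.withdrawal_mode = "per_cycle"`); the one-shot reading is
  available as `"immediate"`.  Both converge to the same long-run occupancy
  (all non-responders eventually resume standard care); they differ only in
  how long non-responders keep paying for irrigation.

* **Background mortality.**  A lifetime horizon needs a survival model, and
  none is published with the clinical parameters.  The engine therefore
  consumes a replaceable life-table CSV (`age`, `qx_male`, `qx_female`).
  The packaged table is *synthetic*: Gompertz–Makeham hazards
  (male \(A = 2\times10^{-4}\), \(B = 1.2\times10^{-5}\), \(\theta = 0.102\);
  female \(A = 10^{-4}\), \(B = 4\times10^{-6}\), \(\theta = 0.110\))
  calibrated to life expectancies of roughly 82 (men) and 87 (women) years
  at birth, in line with contemporary Japanese vital statistics.  An
  excess-mortality multiplier (`settings.excess_mortality_smr`, default 1)
  is applied on the hazard scale for users who wish to model elevated
  mortality after spinal cord injury.  Mortality acts first within each
  cycle; all competing transitions are scaled by the survival probability.

## Accrual conventions

Costs and QALYs are accrued on end-of-cycle occupancy and discounted at
cycle end, i.e. cycle \(t\) is weighted by \((1.02)^{-t/2}\).  A half-cycle
correction (averaging start- and end-of-cycle occupancy) is available via
`settings.half_cycle_correction` but off by default.  With the correction
on, stoma management costs still follow end-of-cycle tenure masses —
the correction applies to state-occupancy accruals.

Per-cycle state costs:

* TAI states: half the annual device cost (280 945 yen/year, i.e. two
  irrigation systems at 12 095 yen plus 180 accessory units totalling
  256 755 yen) plus six months of the procedure fee (18 000 yen/month in
  the base case; 8100 and 13 050 are the published alternatives, settable
  via `settings.tai_procedure_fee_per_month`).
* SBC states: six months of conservative care at 4151 yen/month.
* Stoma: surgery (113 955 yen, the 57.5/42.5 laparoscopic/open weighted
  fee) and surgical hospitalization (239 020 yen weighted the same way)
  charged once to the inflow in the entry cycle; management at
  4131 yen/month for the first year after construction and 1621 yen/month
  thereafter, tracked per entry cohort.

Event costs are added as expected values: the UTI rate times the
treatment-split-weighted episode cost
(0.086·163 113 + 0.811·14 126 + 0.103·10 293 ≈ 26 544 yen), hospitalization
frequencies times 1 512 630 yen (pressure ulcer) or 630 960 yen (other),
and the visiting-nursing rate times a weekly cost of 2 visits × 5800 yen
plus the once-weekly 5200-yen long-hours premium, over 26 weeks.

One parameter needs loud documentation:
**`clinical.hospitalization_recall_years` (default 8.5)**.  The published
hospitalization frequencies (0.31 and 1.73 episodes per SBC patient for
pressure ulcer and other causes) carry no stated period.  Taken per cycle
they would imply four hospitalizations a year and dwarf every other cost.
The model reads them as counts over the respondents' disease duration and
divides by this recall window — 8.5 years, the mean time since diagnosis in
the external TAI cohort used for the responder analysis — before converting
to per-cycle rates.  This is the single most consequential modelling
assumption that the source evidence does not pin down; it is a plain config
field so any other reading can be substituted.

QALYs per cycle are the state utility (responder 0.533, non-responder
0.470, SBC 0.479, stoma 0.564) times the half-year, minus one-off additive
decrements per expected event: 0.060 per UTI episode and 0.010 per
hospitalization.  Decrements are charged in the cycle of occurrence, the
usual convention when event-duration data are absent.  The stoma state
keeps SBC-level event rates and nursing by default (`stoma_events_mode =
"sbc_rates"`); a management-costs-only stoma is available.

## Mapping NBDS to utilities

The state utilities above are packaged constants.  The package also
implements the mapping pipeline that produces such values from survey data:

1. `fit_eq5d_mapping()` fits, per EQ-5D-5L dimension, a multinomial logistic
   regression of the level (1–5) on NBDS with age and a male indicator as
   covariates.
2. `simulate_expected_utility()` repeats virtual experiments: per trial, one
   independent uniform per dimension is inverted through `assign_level()` —
   the smallest level whose cumulative probability covers the draw, exactly
   the five-branch conditional rule — and the profile is valued with a
   tariff.  10 000 trials per NBDS value (0–47) is the default;
   `expected_utility_exact()` provides the 3125-profile enumeration the
   Monte Carlo converges to at rate \(1/\sqrt{\text{trials}}\).
3. `state_utilities_from_curve()` reads utilities off the curve at the state
   scores: baseline 16.74 for SBC, 10.74 (= 16.74 − 6) for responders,
   17.74 (+1) for non-responders, rounded half-up to integer scores.

Covariates are fixed at the cohort means (age 51.46, male fraction 0.783)
during simulation; simulating at individual covariates and averaging is the
main alternative, and with an additive tariff and these nearly linear
fits it changes the curve very little.  The packaged tariff is a *synthetic*
stylized additive value set (full health 1, per-dimension level decrements)
because no national tariff is bundled; `load_value_set()` accepts any
drop-in CSV with the same columns.  RNG streams are keyed by `(seed, NBDS)`
so curves are reproducible and insensitive to evaluation order.

## Derived clinical risks

`relative_risk()` is the plain ratio (0.195/0.512 = 0.381 for UTIs).
`exponential_rate_per_cycle()` is the constant-hazard maximum-likelihood
estimator — events over person-years — converted to a per-cycle probability
\(1 - e^{-\lambda/2}\); respondents without a stoma are censored at their
disability duration.  `fit_nursing_model()` is a logistic regression of the
visiting-nursing indicator on NBDS, age, sex and hand function; the engine
consumes the published 31.8%/19.41% rates directly, and the regression path
exists to regenerate them from survey-style data (hand function is coded as
a binary impairment indicator).

## Sensitivity analysis

`one_way_sweep()` reruns the model at ±20% of each scalar parameter.  It
reports the ICER at both endpoints but **ranks parameters by the width of
the incremental net-monetary-benefit interval at a 5-million-yen reference
willingness to pay**, not by the raw ICER range: utility sweeps of this
model push the incremental QALY through zero, where the ICER has a pole, so
an ICER range measures distance to the pole rather than influence.  NMB is
linear in both increments and gives a stable influence ordering — under the
base calibration the TAI-responder utility weight ranks first, followed by
the SBC utility weight.  Probabilities pushed above 1 by the sweep are
clamped and flagged.

`run_psa()` samples parameters independently: gamma for costs and for
unbounded event frequencies, beta for utilities and probabilities bounded in
\[0, 1\] (the published hospitalization frequencies exceed 1 and therefore
take the gamma).  No dispersion data are published, so the default
coefficient of variation is 0.2, mirroring the ±20% deterministic range and
configurable per parameter; method-of-moments parameterisation, with
infeasible beta variances shrunk to 99% of the bound and flagged.
Correlations between parameters are not modelled.  `ceac()` computes, per
willingness-to-pay value, the fraction of draws with non-negative net
monetary benefit; the default grid is 0–10 million yen in 100 000-yen
steps.

## The synthetic survey generator

`generate_survey()` emulates the 217-respondent patient survey that the
fitting stages were designed for: truncated-normal age (51.46 ± 13.50 on
19–87) and NBDS (16.74 ± 5.72 on 0–47, about 69–71% severe), 78.3% male,
EQ-5D-5L levels drawn from a true multinomial-logit model whose shared
per-dimension NBDS slope shifts mass to worse levels as symptoms worsen,
nursing visits from a true logistic model calibrated so the implied rate is
31.8% at the baseline score and 19.4% at the responder score, exponential
time to stoma with gamma-distributed administrative censoring around 8.5
years, and WPAI-style employment (48.8%), absenteeism and presenteeism by
severity category with beta noise.  `eligibility_filter()` applies the
programmatically checkable inclusion criteria (age > 18, NBDS > 6);
symptom-based criteria are not simulated in detail.

What passing the recovery tests shows: the multinomial, logistic and
exponential estimators recover the generating coefficients (within ±15% at
n = 5000, hazard within 10% at n = 10 000), i.e. the fitting code is
correct.  What it does not show: that real survey data satisfy the
generator's assumptions — dimension independence given NBDS, logistic
functional forms, constant stoma hazard.  The generator reproduces the
printed marginals and the assumed dependence structure, nothing more.

## Numerical choices and problem sizes

Transition-matrix rows are checked to sum to 1 within 1e-12 every cycle;
occupancy conservation is enforced at the same tolerance.  Money is carried
in floating point and reported rounded to whole yen.  The engine runs 118
half-year cycles (age 51.46 to 110) in a few milliseconds, so the test
suite uses full-horizon runs throughout; Monte Carlo components are sized
for stable assertions rather than publication-grade smoothness (10 000
trials for utility-mapping checks, a few thousand PSA draws in scripted
analyses, smaller in unit tests).  Ties in `assign_level()` follow the
left-closed rule (`u ≤ cumulative`), so a draw exactly on a boundary takes
the lower level, matching the five-branch conditional exactly.

## Known limitations

* The ICER level depends materially on the mortality stand-in and the
  hospitalization recall window; both are exposed as data/config rather
  than buried, but they remain assumptions.  Headline QALY totals are
  sensitive to the life table; incremental results are far less so.
* Event disutilities are one-off and additive; no duration-of-episode
  modelling.
* The packaged tariff is stylized; absolute utility-curve levels should not
  be read against published national value sets.
* PSA treats parameters as independent with a uniform CV.
* Cohort (expected-value) model only: no patient-level heterogeneity beyond
  the state structure, matching the design it implements.
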