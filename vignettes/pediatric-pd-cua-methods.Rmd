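---
title: "Methods: a lifetime Markov cost-utility model of pediatric peritoneal dialysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lifetime Markov cost-utility model of pediatric peritoneal dialysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedpdcua)
```

## The model

`pedpdcua` evaluates automated peritoneal dialysis (APD) against continuous
ambulatory peritoneal dialysis (CAPD) for children with end-stage kidney
disease as a pair of four-state Markov cohort models. Each arm's cohort
starts 100% in its assigned PD modality at age one and moves annually
between *PD*, *hemodialysis (HD)*, *kidney transplantation (KT)* and
*death* (absorbing). The two arms share the same state graph; they differ
only in which modality *PD* denotes, in the first-year transition
probabilities, in PD costs, and in the PD utility weight.

Four structural assumptions shape the transition matrix
(`transition_matrix()`):

1. patients never switch between APD and CAPD;
2. failed HD or KT returns the patient to the arm's own PD modality
   (there is no HD→KT edge in the schedule);
3. the probability of transplantation from PD is identical in the two arms
   (enforced as a validation invariant and sampled jointly in the PSA);
4. the transition schedule is stored for model years 1–10 only; the
   year-10 row applies to every later cycle.

A scenario switch (`run_cohort(..., scenario = "year1_forever")`) applies
the year-1 schedule to every cycle instead; it exists because in the data
this model emulates only the first year separates the arms' transition
probabilities, so the scenario stress-tests that single year's influence.

"Lifetime" is operationalized as an age cap of 100 years with early
termination once the surviving fraction falls below 1e-6. With the default
start age of one this is at most 99 one-year cycles.

## From survival curves to transition probabilities

Transition probabilities are derived from annual survival probabilities
S(t) by the standard chain (`survival_to_cycle_probs()`): conditional
survival S(u) = S(t)/S(t−1), per-cycle event probability tp(t) = 1 − S(u),
conversion to a rate r = −ln(1 − tp(t))/cycle, and back to a probability
1 − exp(−r·cycle). With one-year cycles the rate round trip is the exact
identity; both steps are implemented and tested as mutually inverse so that
other cycle lengths remain correct. A year in which survival reaches
exactly zero yields probability 1, handled explicitly rather than through
floating-point overflow; a curve that sits at zero with later years present
is rejected as degenerate.

Short observed curves (years 1–3) are extended to year 10 with the
year-2→3 survival ratio q = S(3)/S(2) applied multiplicatively:
S(t) = S(t−1)·q (`extrapolate_survival()`). The multiplicative reading of
"observed survival decrease" was a genuine design choice: an absolute
annual decrement can drive survival negative on long horizons, while the
constant-ratio form is equivalent to a constant hazard and keeps the curve
in [0, 1] for any horizon. It also has the convenient, tested consequence
that the extrapolated tail produces a constant per-cycle probability 1 − q.

Disease-specific death probabilities merge with age-specific background
mortality under independent competing risks,
1 − (1 − p_state)(1 − p_background) (`combine_mortality()`). The merging
rule is another open design point — replacement and capping are defensible —
so a `max(p_state, p_background)` alternative is available via
`mortality_rule = "max"`; competing risks is the default because it never
understates either risk and is symmetric. If a row's exits exceed 1 after
merging, the engine raises an error naming the state, arm, schedule year
and age rather than silently truncating.

## Accrual and discounting

Costs and utilities accrue to the state occupied at the start of each
cycle, discounted by (1 + r)^−t with t = 0 for the first cycle
(first cycle undiscounted). This convention is common in published
cohort cost-utility models; nothing in the emulated analysis pins down the
alternative (t starting at 1), and the difference is a uniform factor
1/(1 + r) on every stream, well inside the reproduction tolerances used.
No half-cycle correction is applied by default (none is part of the
emulated analysis); `half_cycle_correction = TRUE` switches accrual to the
mean of start- and end-of-cycle occupancy.

Cost parameters are annual, in 2022 Thai baht, split into direct medical
costs in the first year (`dmc_y1`), direct medical costs in later years
(`dmc_y2plus`), and direct non-medical costs (`dnmc`, all years). For the
PD modality and HD the first-year/later-year selection is indexed by time
since model start — matching the convention in which sensitivity-analysis
parameters are labelled "costs from year 2 onward". For KT it is indexed by
time since transplantation, tracked with a one-cycle tunnel compartment,
because the transplant-year cost (surgery, induction) is structurally
different from maintenance immunosuppression and would be meaningless if
tied to calendar time. The cohort trace reports the two KT compartments
collapsed into one state.

Default rates: 3%/year for both costs and outcomes (allowed range 0–0.10);
willingness to pay 160,000 baht/QALY, the Thai HTA threshold.

## Comparison

`compare_strategies()` computes incremental cost, life years and QALYs
(APD − CAPD) from unrounded totals; ICERs are reported per QALY and per
life year. Published-style tables round to two decimals at the
presentation layer only — the printed incrementals 0.46 QALY and −0.05 LY
in the emulated analysis are only consistent with division performed
before rounding. Dominance is labelled per effect axis (a strategy can be
dominated on life years yet buy QALYs, which is exactly the base-case
pattern here); an ICER with zero incremental effect is reported as
undefined rather than an error. `net_monetary_benefit()` provides
NMB = WTP·QALY − cost, and the two-strategy identity "NMB(APD) > NMB(CAPD)
iff APD is cost-effective at that WTP" is property-tested.

## Uncertainty analysis

**One-way (tornado).** Every parameter carrying a 95% CI is set in turn to
each bound, everything else held at base, and the full two-arm model is
re-run (`one_way_sa()`). Entries are sorted by the width of the ICER range,
ties broken by parameter id. Parameters without a CI are excluded — treated
as fixed. The discount rates carry no CI; they are varied over a
conventional 0–6% range (configurable, or excludable with
`discount_range = NULL`). Bounds that would leave a parameter's support are
clamped with a warning.

**Probabilistic.** `run_psa()` samples all uncertain parameters
independently each iteration: beta distributions for probabilities and
utilities, gamma for costs, fitted by method of moments from the point
value and the 95% CI with SE = (high − low)/3.92. These families are
standard HTA practice for parameters on [0, 1] and [0, ∞); the emulated
analysis names none, so the choice is ours and is overridable by editing
the fitted families. An infeasible beta fit (CI so wide the implied
variance exceeds m(1−m)) falls back to a uniform draw over the CI with a
warning at fit time. Because draws are independent, a sampled transition
row can exceed unit exit probability; such rows are rescaled
proportionally, a repair that is deterministic and tested. Parameter
correlation is not modelled. The PSA is reproducible bit-for-bit given its
seed; seeding is scoped (`with_seed()`) so package functions never disturb
the caller's RNG stream.

**CEAC.** At each willingness-to-pay value the probability that an arm is
cost-effective is the fraction of draws in which its net monetary benefit
is strictly larger, with ties split equally — hence the two probabilities
sum to exactly 1. The default grid spans 0–400,000 baht in 10,000-baht
steps and always includes 160,000.

## Budget impact

The budget-impact module works from the government perspective: direct
medical costs only, no discounting, 100% first-year uptake. The pediatric
PD population advances by
n(y+1) = n(y)·(1 − p_KT − p_HD − p_death) + incident(y+1), with defaults
p_KT = 0.079, p_HD = 0.031, p_death = 0.023 and 61 incident cases/year; an
all-age incidence series can be converted through the pediatric proportion
(0.004) and PD probability (0.76). Counts stay unrounded in the recurrence
and are rounded to whole patients at report time.

The published table this module reproduces follows a specific rounding
pipeline, recovered by matching all ten printed rows: the two budget
columns are each rounded to integer millions of baht; the *incremental*
column is rounded to millions from the **unrounded** budget difference
(n·Δc/10^6 — in two of the ten years this differs by 1 M from subtracting
the printed budget columns); and the net budget impact per patient divides
the rounded incremental budget by the patient count. Averages are plain
means of the yearly rounded values, rounded again. `compute_bia()`
implements this as `rounding = "printed"` and offers an unrounded
`"exact"` mode, under which the per-patient net budget impact is constant
at the unit-cost difference (63,195 baht with the default costs).

## Synthetic data and verification

`generate_parameter_set()` draws complete random parameter sets that
emulate the real model's statistical structure: PD mortality derived from
monotone survival curves with a constant-ratio tail, years 2–10 shared
between arms (only year 1 separates the modalities, as in the emulated
data), a shared PD→KT probability, per-state exit sums kept below 1,
gamma-distributed positive costs, utilities in [0, 1] with u(APD) ≥ u(CAPD)
by default, and a background mortality table rising roughly exponentially
with age. An `edge` flag pushes probabilities toward 0/1 for fuzzing. The
generator is the test-bed for every engine invariant (probability
conservation, absorbing death, discount monotonicity, serialization round
trips).

The engine's independent check is `microsim_oracle()`: an individual-level
Monte Carlo simulation pushing patients one at a time through the same
one-cycle matrices (including the KT tunnel) and averaging discounted
outcomes. The cohort engine's totals must agree with the oracle's means
within three Monte Carlo standard errors; the test suite runs this at
200,000 individuals on five random parameter sets with 15-cycle horizons —
sizes chosen to keep the whole suite around ten seconds while leaving the
standard errors small enough to be a meaningful check (the z-statistic is
also recomputed by the acceptance script).

What the synthetic generator does **not** emulate: correlation between
parameters, time-varying utilities (for instance the utility improvement
in the second year after transplantation, deliberately out of scope),
modality switching, or patient-level heterogeneity. Passing tests
therefore certify the arithmetic of the pipeline on structurally realistic
inputs, not the clinical realism of any particular synthetic value.

## Parameter provenance

The packaged fixture (`pd_example_params()`) merges two files: a main-text
transcription (PD utilities 0.8900/0.9400, PD direct medical costs, 3%
discounting, the WTP threshold, and every budget-impact input) and a
supplementary *template* whose rows — the full transition schedule, HD/KT
costs and utilities, background mortality — are synthetic placeholders
tagged `synthetic_placeholder` and named accordingly. Every parameter row
carries a provenance tag, and `is_transcribed()` gates any analysis that
claims to reproduce the published base case: with placeholders present,
those checks skip with an explanatory message and the property suite above
is the meaningful acceptance surface. Replacing the template's values with
a transcription of the real supplementary table (retagging rows
`supplementary_transcribed`) activates them. The main-text utility and
cost rows carry synthetic CI bounds (the body text prints point values
only); this is recorded in the fixture file's own notes field.

## Known limitations

- Two strategies only; no efficiency frontier over three or more.
- No expected value of perfect information.
- No CPI adjustment: all cost inputs are assumed to be in same-year baht.
- HD first-year costs are indexed by time since model start, not state
  entry; for cohorts that reach HD late, `dmc_y2plus` dominates, which is
  the intended reading of the emulated parameter structure but is a
  modelling convention, not a clinical fact.
- The budget-impact projection treats attrition probabilities as constant
  over the decade and applies no uptake ramp.
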