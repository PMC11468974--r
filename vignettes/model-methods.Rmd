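---
title: "Methods: a closed-cohort Markov cost-utility model for nationwide physical-activity programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a closed-cohort Markov cost-utility model for nationwide physical-activity programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepscea)
```

## The decision problem

Nationwide incentive-based step challenges aim to raise population physical
activity (PA) and thereby delay the onset of diabetes and hypertension, their
major complications, and premature death. Whether the health gains justify the
program's cost is a cost-utility question: we compare a situation in which the
program runs every year for a decade against a no-program comparator, and
summarise the difference as QALYs gained, cases and deaths averted, health-care
and societal cost reductions, and an incremental cost-effectiveness ratio
(ICER, SGD per QALY gained).

`stepscea` implements this comparison as a deterministic Markov cohort model
with a full uncertainty workbench: probabilistic sensitivity analysis (PSA)
with cost-effectiveness acceptability curves, one-way deterministic (tornado)
sensitivity, threshold (break-even) analysis, and a cost-differentiation
scenario.

## State space and transitions

Twelve states: `healthy`, `diabetes` and `hypertension`, each split into three
PA levels (`inactive`, `low`, `mod_high`, with inactive the reference level
for every relative risk); one chronic complication state per disease
(cardiovascular disease for diabetes, stroke for hypertension) without a PA
level; and absorbing `dead`. Comorbidity is excluded by construction — a
member of the diabetes branch can never enter a hypertension state — and
complication states admit only self-loop and death (no recovery, no direct
healthy-to-complication transition; onset passes through the uncomplicated
disease state).

Within a one-year cycle, events are composed in a fixed order:

1. **PA-level shift.** A 3×3 row-stochastic annual matrix acts on each
   PA-carrying block. Under the intervention, a compliant fraction of the
   cohort follows the intervention shift matrix and the remainder the control
   (secular) matrix; the effective shift is the compliance-weighted mixture.
   The control default is the identity (no secular drift), flagged in the
   configuration so a drift matrix can be supplied.
2. **Disease and complication onset.** Annual onset rates are adjusted by the
   PA-level relative risk on the *rate* scale and converted to probabilities
   with `1 − exp(−rate)`, which keeps probabilities in [0, 1) for any relative
   risk. Competing onsets from healthy must sum to at most 1; a violation is a
   parameter-inconsistency *error*, never a silent renormalisation.
3. **Death.** All-cause mortality times a group-and-PA-specific relative risk
   (a scalar multiplier in the complication states).

The one-cycle matrix is the product of the three stage matrices; since each
stage is row-stochastic, so is the product (verified to 1e-12 over 1000
random parameter sets in the test suite). The order itself is a modelling
choice — the three stages do not commute — and fixing it makes the
individual-level simulation oracle well defined; reversing onset and death
would change transition masses by O(rate²), well inside parameter uncertainty.

**Calibration.** Inputs give *population-average* incidence per age band, but
the model needs the inactive-reference rate. `calibrate_baseline_incidence()`
solves the one-unknown linear equation: the prevalence-weighted average of
`rr × i₀` over the baseline PA mix equals the observed rate. Disease onset is
calibrated against the healthy group's PA mix, complication onset against the
corresponding disease group's mix.

## Cohort, ageing, accumulation

The cohort is closed: registrants times the completion fraction (base
1.7 million × 0.385 = 654,500), distributed over 5-year age bands (17–19,
20–24, …, 85+) by the census-style age distribution, and within band by
disease prevalence × PA prevalence. Each band's sub-cohort ages one year per
cycle (represented by the band midpoint) and uses the transition matrix of
whatever band its current age falls in; the final band is open-ended.

Costs and QALYs are accumulated with half-cycle correction — person-years in
cycle *t* are the trapezoid of occupancy at boundaries *t−1* and *t* — and
discounted at 3% per annum with end-of-cycle timing, `(1+r)^−t`. Mid-cycle
timing (`(1+r)^−(t−1/2)`) is selectable via `discount_timing: mid`; we default
to end-of-cycle as the common textbook pairing with half-cycle-corrected
flows. Under this convention a SGD 36M annual program cost discounts to
36 × 8.5302 ≈ SGD 307.1M over ten years. Program cost is not
state-dependent, accrues only under the intervention, is discounted without
half-cycle correction, and is always reported separately from health-care
cost.

Annual direct cost in an uncomplicated disease state is
`inpatient_proportion × inpatient + (1 − inpatient_proportion) × outpatient`;
complication states are costed as all-inpatient. Indirect (societal) cost is
direct cost divided by the disease's direct-to-indirect ratio. Healthy states
carry no treatment cost. Incident counts (new diabetes, new hypertension, new
complications, deaths) are probability-mass flows read off the staged
matrices each cycle; "cases prevented" are differences of *cumulative incident
flows* (control − intervention), not prevalence differences.

## Economics

The ICER is `(program cost − cost reduction) / QALYs gained`. The program is
*cost-saving* when QALYs gained are positive and the health-care cost
reduction exceeds the program cost, i.e. exactly when the ICER is negative
with positive QALYs; `classify_icer()` labels the other quadrants
(`dominated`, `undefined`) rather than reporting a bare ratio, and a zero QALY
gain yields an `NA` ICER with an `undefined` attribute. The probability of
cost-effectiveness is computed by net monetary benefit,
`P(wtp × ΔQALY − ΔCost > 0)`, which coincides with the proportion of
per-sample ICERs below the threshold whenever every sample gains QALYs — the
regime this model operates in — while remaining well defined for mixed-sign
QALY draws.

## Uncertainty analyses

**PSA.** All uncertain parameters (33 in the full-scale set) are drawn jointly
and independently, except the time horizon, which is never sampled (it is a
policy choice, not a parameter). Each parameter owns an RNG stream derived
from the master seed and its table position, so adding or removing a
parameter does not perturb the others' draws — this keeps regression tests
stable. Families follow health-economics convention: beta for probabilities
and utilities, gamma for costs, lognormal for relative risks; draws are
truncated to the parameter's domain, and after each joint draw the structural
utility ordering (complication ≤ parent disease ≤ healthy) is restored by
truncation at the boundary. Cohort size varies with the drawn compliance
(registrants × compliance), so the simulated cohort carries a credible
interval. Summaries are sample means and 2.5/97.5 percentiles computed on the
raw samples with linear interpolation between order statistics (R's type-7
rule, fixed and documented).

**One-way DSA.** Each parameter in turn is set to its low and high bound —
95% distribution quantiles by default, the interquartile range for treatment
costs, ±30% for inpatient proportions, program cost, compliance and horizon —
with the rest at base values; entries are sorted by `|ICER_high − ICER_low|`.
Horizon bounds are rounded to whole cycles (7 and 13 years for ±30% of 10).
Bounds that overshoot a parameter's domain are clamped with a warning.

**Threshold analysis.** Bisection on the deterministic ICER as a function of
one parameter, to a bracket-width tolerance of 1e-6 of the initial bracket;
the returned root is verified by direct model evaluation, and its direction
(`at_least` / `at_most`) is read from the sign pattern. Absence of a sign
change is a signal, not an error.

**Scenario.** `apply_cost_differentiation(params, 0.05)` inflates the
inactive level's annual costs by 5% and deflates the moderate-to-high level's
by 5% within each uncomplicated disease state (complications are unchanged);
the base case assumes equal costs across PA levels. With an upward PA shift
this mechanically increases the measured cost reduction.

## The synthetic parameter generator

The study-scale parameter table is not redistributable, so
`generate_parameter_set()` produces complete, schema-valid stand-ins. The
anchors that are fixed by the program's design are used verbatim: SGD 36M/yr
program cost, 0.385 compliance/completion, 1.7M registrants, 3% discount,
10-year horizon, WTP grid {0, 5000, 10000}. Everything else is drawn once
from documented plausible ranges for an adult Asian urban population —
Gompertz-like mortality (2e-4 at age 18 rising to ~7% at 87), adult diabetes
onset averaging roughly 1%/year and hypertension roughly 2%/year, complication
onset of 2–3%/year from the disease states, protective PA relative risks of
0.66–0.89, utilities 0.94/0.84/0.87 for healthy/diabetes/hypertension with
complication decrements, and complication inpatient costs about 1.8× the
uncomplicated inpatient costs. Per-seed multiplicative jitters (±4–10%)
differentiate seeds while all qualitative constraints hold by construction.
These magnitudes were chosen once, at design time, so that the base case sits
in the qualitative regime the program analysis reports: cost-saving at base
compliance, a compliance break-even slightly below base, a complication-cost
break-even below its base value, and a horizon break-even at ten years.

What the generator does *not* emulate: correlated parameter uncertainty,
secular trends in incidence or mortality, age-dependent relative risks, open
cohort entry, or the value identities of the study's table. A passing
pipeline therefore demonstrates the machinery — calibration, propagation,
accumulation, uncertainty analysis — on structurally faithful inputs, not a
reproduction of the study's point estimates, which would require transcribing
its supplementary table into a configuration file via `read_config()`.

The individual-level `microsim_oracle()` is an independent implementation of
the same state process (same matrices, same event order, per-individual
sampled paths) and must agree with the cohort engine within Monte Carlo
error; the tests require agreement within 3 standard errors at 10,000
individuals, alongside exact closed-form checks (geometric-series annuity,
hand-composed matrices, conservation at 1e-6 persons).

## Numerical choices and problem sizes

- Rates ≥ 0 everywhere; `rate_to_probability()` rejects negative rates.
- Row-stochasticity tolerance 1e-12; cohort conservation 1e-6 persons.
- Ties and degenerate inputs: degenerate distributions are legal everywhere
  (the PSA then reproduces the deterministic run exactly); an all-dead cohort
  makes projected prevalence an explicit error.
- Headline numbers are rounded to three significant figures only at the
  presentation layer (`headline_format()`); all stored values keep full
  precision, and every results file records the seed and the configuration
  file's MD5 hash.
- Test problem sizes: the toy scale (3 age bands) backs the exact-arithmetic
  and property tests; full-scale runs use the 15-band set with cohorts of
  10⁴–6.5×10⁵ persons; PSA convergence tests use 30–200 samples and the
  reproduction script uses the study's 1000.

## Limitations

Only two diseases with one complication each; no comorbidity; no PA level in
the complication states; closed cohort (no later joiners); constant program
cost and no cost inflation; independence across uncertain parameters; and the
synthetic parameter values are stand-ins, so absolute outputs under the
default generator are illustrative rather than estimates for any real
population.
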