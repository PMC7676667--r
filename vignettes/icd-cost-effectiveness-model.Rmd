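---
title: "A Markov cohort model of ICD cost-effectiveness: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of ICD cost-effectiveness: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icdcea)
```

## The decision problem

Implantable cardioverter defibrillators (ICDs) prevent death from sudden
cardiac arrest in heart-failure patients, but the device, its implantation
and its maintenance are expensive. From a payer's perspective the question
is whether the survival and quality-of-life gains justify the cost, and for
which patients. `icdcea` models that trade-off for two indications: the full
primary-prevention (PP) population, and the 1.5-primary-prevention (1.5PP)
subset — PP patients with at least one additional risk factor
(non-sustained VT, frequent PVCs, LVEF below 25%, or (pre)syncope) — using
Taiwanese payer costs in 2017 NT$ and a willingness-to-pay (WTP) threshold
of NT$2.1 million per QALY.

## Model structure

Each population is evaluated under two strategies, ICD therapy and no ICD
therapy. A decision-tree implant node starts the ICD arm: a fraction
(`operative_death_initial`, 0.0002) dies at surgery, the remainder enters a
monthly-cycle Markov model in the well state. The state space of the ICD arm
is

* `well_initial` / `well_replacement` — alive with the first or a
  replacement device (the phases differ in complication hazards),
* `complication` — a one-cycle tunnel entered through an inappropriate
  shock, lead replacement, lead dislodgement or device infection,
* `discontinued` — alive after abandoning ICD therapy (only reachable from
  the tunnel, via the discontinued-therapy shock pathway), subject to the
  no-ICD arm's mortality from then on,
* four absorbing cause-specific death states, plus operative death and an
  optional background-mortality death state.

The no-ICD arm has a single well state and the death states. Transitions
compete as a direct multinomial per cycle: the four cause-specific monthly
probabilities are used exactly as parameterized (their sums are far below
1), not converted through rates. Cohort occupancy is propagated
deterministically for 420 monthly cycles (a lifetime horizon); every row of
the trace sums to one, and the engine raises a structural error if any
state's exit probabilities exceed one.

Device replacements are instantaneous costed events, not states: at every
multiple of the replacement interval the surviving well occupancy switches
to the replacement phase and incurs the replacement procedure cost.
Operative death applies only at the initial implant by default
(`apply_operative_death_at_replacement` exposes the alternative).
Tunnel occupants at a replacement epoch rejoin the replacement-phase well
state on exit without paying for a device that cycle; the mass involved is
below 1% of the cohort.

## Parameters

All inputs live in two YAML configurations, `pp.yaml` and `pp15.yaml`
(`icdcea_config()`), with `value`/`se`/`dist`/`basis` keys per field.
Because the published inputs mix time bases, each event probability carries
an explicit `basis`:

* `monthly` — shock probabilities (0.0034 continue / 0.0001 discontinue)
  and lead replacement (0.0004 initial, 0.0008 after replacement; the
  source annual incidence of 0.45% divided by 12 matches the initial
  value's magnitude);
* `annual` — lead dislodgement (1.8% first year after implant, 0.5% after
  replacement), converted by `1 - (1 - p)^(1/12)`;
* `phase_lifetime` — device infection (2.44% per initial-device phase,
  4.32% per replacement phase, i.e. double the one-year claims-based
  probabilities), spread as a constant hazard over one replacement
  interval.

Costs are one-off event costs plus monthly inpatient (NT$6,828) and
outpatient (NT$858) maintenance accrued by every alive patient in both
arms. Each infection event additionally carries the generator-removal cost,
removal being the standard management of device infection (the mapping is a
config choice, not hard-coded).

Quality of life uses the annual utility of the well state (0.7315 PP,
0.8683 1.5PP) divided by 12 per cycle; the tunnel cycle uses the
complication-state utility (0.6474 / 0.7685); and every complication event
— shocks and the rarer lead/infection events alike — subtracts an absolute
short-term decrement of 0.096 lasting 3.5 days (0.096 × 3.5/365.25 QALYs).
Discounting compounds in months, `(1 + r)^(-t/12)` at r = 1.375%/year, so
it is exact at annual boundaries; cycle-0 events (implant, operative death)
are undiscounted. Accrual uses end-of-cycle occupancy; a half-cycle
correction flag exists but is off by default, matching the published
totals.

## Background mortality and calibration

The cause-specific monthly probabilities are constant over the horizon.
Extrapolated over 35 years, constant hazards estimated from a trial
population in its early sixties understate the mortality of an ageing
cohort: the 1.5PP no-ICD closed form gives about 10.8 undiscounted
life-years where the published model reports 9.82. The engine therefore
supports an age-indexed background-mortality mode driven by a life table:

* `off` — constant hazards only;
* `additive` — the full life-table annual risk at the cohort's current age
  is added as a competing monthly hazard;
* `excess` — only the *increase* of the life-table risk over its value at
  the entry age (61.1 years, the trial cohorts' mean age) is added, so the
  cause-specific inputs keep describing the cohort at entry and the life
  table contributes only ageing.

The packaged life table (`life_table_taiwan_synthetic.csv`) is a synthetic
Gompertz curve, q(age) = 0.007 · exp(0.095 · (age − 60)) per year, chosen
as a realistic stand-in for Taiwanese general-population mortality in the
relevant age range; it is synthetic and so labelled because the package
ships no third-party data.

The published base value of the device replacement interval is not
reported (it appears only as a one-way sensitivity axis), and modern ICD
generator longevities span roughly 6–10 years. The packaged configurations
ship the calibrated structural setting — `excess` background mortality at
entry age 61.1 with the Gompertz table above, and a 96-month replacement
interval — selected once by a grid over exactly these exposed knobs so
that the reproduced base-case quantities sit within a few percent of the
published table (all within ±5%, most within ±2%). With background
mortality `off` and a 72-month interval the engine reproduces the
plain constant-hazard reading instead; incremental QALYs then overshoot by
20–40% even though the ICERs move much less, which is why the calibrated
setting is the default. The cost-effectiveness ordering (1.5PP below PP,
both below the WTP threshold, 1.5PP below a third of it) holds under both
settings.

## Sensitivity analyses

One-way sweeps (`one_way_sweep()`, `tornado()`) re-run the whole pipeline
at substituted parameter values. Scale pseudo-paths (`@scale` on the
`mortality_no_icd`, `utilities` or `costs` block) vary a whole block by a
multiplier, which is how the conventional-mortality, quality-of-life and
cost axes are defined; ranges without a published counterpart default to
±20% (the utility upper multiplier is 1.15 so the 1.5PP annual utility
stays below 1), the age axis spans ±10 years, and the replacement-period
axis spans 48–120 months.

The probabilistic analysis (`run_psa()`) draws every probability and
utility from a beta distribution parameterized by method of moments from
its reported mean and standard error — the standard choice when only two
moments are published. Costs are fixed (no cost distributions are
reported), as are the entry age and replacement interval. Mortality causes
are drawn independently with a joint rejection if their sum reaches 1
(never triggered at these magnitudes, but the invariant is enforced). A
value/SE pair admitting no beta distribution (se² ≥ m(1−m)) would be held
at its base value; none of the packaged inputs needs this guard.

Two cost-per-QALY summaries are reported. `icer_at_means` — mean
incremental cost over mean incremental QALYs — is the expectation-based
ICER, the stable headline statistic of a probabilistic analysis; the
per-iteration ratio distribution is strongly right-skewed (small sampled
QALY gains inflate the ratio), so its mean sits well above its median and
depends heavily on the tail. Percentile summaries (median, 95% credible
interval, and the per-iteration mean) are computed over the north-east
quadrant iterations (both differentials positive), where the ratio is
order-meaningful; other quadrants are tallied separately. The fractions of
iterations below the WTP threshold and below a third of it are evaluated
through the net-monetary-benefit sign, so a dominant iteration counts as
cost-effective. `ceac()` generalizes the same quantity over a WTP grid.

## The microsimulation oracle

`simulate_patients()` is a patient-level Monte Carlo simulator that uses
the *same* internal per-cycle probability objects as the cohort engine —
single source of truth, so a disagreement can only come from transition or
accrual bookkeeping, not from parameterization drift. Patients advance
cycle-synchronously in vectorized draws from one seeded stream; results are
reproducible from the seed. `compare_to_cohort()` z-scores the simulated
alive fractions at selected cycles and the discounted cost/life-year/QALY
means against the deterministic values (|z| ≤ 3 passes; fewer than 1,000
patients yields an "insufficient precision" flag instead of a verdict). At
100,000 patients both arms of both populations agree within a fraction of
a Monte-Carlo standard error, which is the package's core validation
property. The simulator emulates the model's own stochastic process — it
shares every structural assumption, so agreement validates the arithmetic,
not the model's fidelity to real patients.

`generate_fixture_param_sets()` produces randomized valid parameterizations
(probabilities log-uniform over [1e-4, 0.05], costs uniform within the
packaged magnitudes, utilities in [0.4, 1]) for property-based testing of
conservation, monotone mortality, the tunnel property and cause-wise
dominance.

## Numerical choices and degenerate inputs

* Row conservation is enforced to 1e-12 at matrix construction and 1e-9
  along the trace.
* With every hazard zero the transition matrix is the identity except the
  complication row: the tunnel's forced exit takes precedence, returning
  its (necessarily zero) occupancy to the well state.
* A zero complication-entry probability makes the tunnel routing fraction
  0 by convention (no 0/0).
* Negative per-cycle utility (possible only under extreme sweep inputs) is
  clamped at zero with a warning.
* The life table is linearly interpolated in age and clamped at its end
  points; entry ages below its first row therefore contribute no excess
  hazard until the cohort ages into the table.
* Problem sizes: the shipped analyses use the full 420-cycle horizon; unit
  tests shorten horizons where only relative behaviour matters, and the
  microsimulation checks use 20,000 patients in unit tests and 100,000 in
  the acceptance suite.

## Known limitations

* The cause-specific hazards are constant (no covariates, no time-varying
  treatment effect); all age dependence enters through the background
  life-table mode.
* The synthetic life table is a single Gompertz curve for both sexes; the
  modelled cohorts are ~76–80% male and have heart failure, so the curve is
  a calibration device, not a demographic claim.
* Exactly two strategies per comparison; no frontier analysis, no EVPI, no
  correlated sampling.
* The replacement interval and entry age are excluded from the PSA (no
  published distributions); they appear in the one-way analysis only.
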