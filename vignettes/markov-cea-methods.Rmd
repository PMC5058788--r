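---
title: "Methods: a three-state Markov cohort model for biologic strategies in metastatic colorectal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-state Markov cohort model for biologic strategies in metastatic colorectal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The decision problem

First-line treatment of metastatic colorectal cancer (mCRC) combines a
chemotherapy backbone (FOLFOX or FOLFIRI) with a biologic: Cetuximab
(anti-EGFR, for RAS wild-type tumours only) or Bevacizumab (anti-VEGF).
Because extended RAS testing restricts Cetuximab to the patients who can
benefit, the testing policy itself has economic consequences. The package
evaluates eight strategies across two analyses built on the CALGB 80405
trial: analysis 1 crosses the biomarker policy (KRAS exon-2 wild-type vs
extended RAS wild-type) with the two biologics on the pooled
physician-choice backbone; analysis 2 crosses the backbone with the
biologic in the extended RAS wild-type population. Costs reflect a
Chinese health-care payer setting (all CNY amounts converted at a fixed
6.15 CNY/USD).

## Model structure and assumptions

Each strategy is a Markov cohort model with three mutually exclusive
states — stable disease (SD), progressive disease (PD) and death — on a
1-month cycle. The cohort starts entirely in SD. Under the default
`progression_required` structure patients leave SD only by progressing,
and die only from PD. This choice keeps the model identifiable from the
two published medians: with only median PFS and median OS available, the
SD-exit hazard is pinned by PFS and the PD-to-death hazard by the
post-progression median OS − PFS. A `direct_death` variant (SD-to-death
at the OS rate, progression at the residual rate) is selectable for
structural sensitivity.

Medians become per-cycle probabilities through the memoryless
(exponential) assumption:

$$P = 1 - 0.5^{1/m} = 1 - e^{-R}, \qquad R = \ln 2 / m,$$

for a median of $m$ months. Decomposing OS as PFS plus an exponential
post-progression phase asserts memorylessness at progression; this is the
standard convention when only medians are published, but it is an
assumption, not an estimate — no survival-curve fitting is possible
without patient-level or digitised Kaplan–Meier data, which is why none
is attempted.

## Accrual, discounting and termination

Within a cycle, each state's occupancy accrues its per-cycle cost and
$u/12$ QALYs (utility $u$: 0.85 in SD, 0.65 in PD, 0 when dead) at cycle
start, multiplied by the cycle's discount factor; the transition matrix
applies at cycle end. Discounting uses the compound-equivalent monthly
factor $(1.03)^{-t/12}$ for the 3% annual base rate (a simple monthly
conversion is selectable). Half-cycle correction is off by default —
accrual at cycle start, transition at cycle end, matching common
decision-software defaults — and available by flag, implemented as
trapezoidal averaging of start- and end-of-cycle occupancy.

The "lifetime" horizon is operationalised as 240 monthly cycles (20
years) with early stopping once dead-state occupancy reaches 0.999. With
the base-case medians the cohort is ≥ 99.9% absorbed within 206–230
cycles, and doubling the horizon moves totals by less than 0.01%. If the
cap binds before absorption the trace is truncated with a recorded
warning rather than silently.

Engine totals are verified against an analytic oracle
(`closed_form_expectation()`): the discounted occupancy sums of the
two-phase absorbing chain are finite geometric series, so expected cost
and QALYs have closed forms. One closed form covers both structures,
because SD-to-death mass simply never feeds the PD inflow term.

## The cost model

Per-cycle SD cost is assembled from components (itemisation is preserved
and always sums to the totals):

- **Biologic drug cost** from dosing arithmetic — Cetuximab 250 mg/m²
  weekly (400 mg/m² loading at the first administration) at 1.60 m² BSA;
  Bevacizumab 5 mg/kg biweekly at 58 kg — times a unit price in USD/mg.
  The unit prices (7.568875 Cetux, 8.996517… Bev) are *derived*
  calibration values: published per-administration costs divided by the
  administered dose, so the dosing arithmetic reproduces $3,027.55 /
  $4,844.08 / $2,608.99 exactly, and the loading/regular ratio equals the
  dose ratio 1.6.
- **Backbone chemotherapy** per biweekly administration ($1,275.69
  FOLFOX, $1,171.77 FOLFIRI, both published; the pooled backbone of
  analysis 1 uses their mean, an assumption).
- **Schedule conversion** onto the monthly cycle uses the average
  calendar month of 365.25/12 days (convention; the source is silent).
- **Administration/monitoring** per cycle (assumed, identical across
  strategies, in the editable calibration file).
- **Societal costs**: travel $8.0 and one absenteeism day at $18.94 per
  visit, with visits at the more frequent of the two schedules.
- **Adverse events**: grade-3/4 incidences per arm are published; unit
  costs are calibration inputs. The hematologic unit cost is solved per
  arm so the incidence-weighted total matches the published arm-level AE
  aggregates, and the on-treatment duration is the implied ratio of the
  published total to the published monthly AE cost (8.46 months Cetux,
  7.39 Bev). The published aggregates cannot be reproduced with unit
  costs shared across arms, which is why the solve is per-arm; every such
  value is labelled `derived` with its provenance note. AE costs accrue
  during SD (on-treatment) only.
- **PD cost**: a single weighted subsequent-therapy cost per month
  (assumed calibration value) plus the monitoring and societal fees,
  which continue during progression.

The first SD cycle adds the loading-dose increment once. All
calibration values live in `cost_calibration.yaml` with
`status ∈ {published, derived, assumed}`; nothing unpublished is
hard-coded.

## Two report modes

The published per-strategy totals (e.g. $140,920.25 and 1.87 QALYs for
RAS-Bev) are not reproducible from first principles at this distance: the
original unit-cost tables and the exact accrual/termination convention
are not recoverable, and the published QALYs sit closer to a simple
median-partition arithmetic than to the geometric-chain expectation.
The package therefore separates two surfaces:

- **published mode** treats the published totals as inputs and computes
  the ratio, dominance, incremental and willingness-to-pay arithmetic
  from them — this reproduces all eight published cost/QALY ratios and
  the ICER of $420,700.50 exactly (rounding half away from zero at 2
  decimals, the reporting convention);
- **engine mode** recomputes totals from the parameter fixtures via the
  cohort engine and reports them next to the published figures with
  explicit deviation columns. The deviation is surfaced, never hidden,
  and engine mode makes no claim to reproduce the published totals.

One fixture decision deserves note: the backbone-specific FOLFIRI medians
are published in a sentence whose ordering is ambiguous; we read them as
FOLFIRI-Cetux 32.0 / FOLFIRI-Bev 35.2 months, the reading consistent with
the reported hazard ratio above 1 for Cetuximab, with the stated
advantage for Bevacizumab, and with FOLFIRI-Bev having the highest
published QALY total. Backbone-specific PFS was never published, so both
analysis-2 backbones reuse the pooled extended-RAS-wt PFS (11.4/11.3
months), marked `assumed` in the provenance table.

## Sensitivity analysis

**One-way (tornado).** Each parameter is set to its low and high value in
turn, the full pipeline re-runs, and entries are sorted by outcome
spread. Supplied ranges are validated (`low ≤ base ≤ high`); absent a
range file, defaults of ±20% around base apply — the published range
tables are not available — truncated where invariants bind (utilities at
1 and at each other, median PFS below median OS). Evaluation at
(base, base) is bit-identical to the base case, and the spread for a
parameter the outcome cannot depend on is exactly zero.

**Monte Carlo.** The published description ("10,000 individuals and 1000
trials") does not say whether parameters were redrawn per trial; the
default here is *first-order* microsimulation — fixed parameters,
individual paths sampled by monthly Bernoulli transitions with the same
accrual conventions as the cohort trace — because that matches the
individual-level phrasing, with a second-order mode available through a
user-supplied parameter sampler. Per-trial RNG substreams derive
deterministically from (seed, trial), so outputs are reproducible and
embed their seed. First-order grand means converge to the cohort-trace
totals; tests assert agreement within 3 standard errors at 10,000
individuals × 50 trials.

One published sensitivity figure is flagged as unreproducible: for the
stable-state utility of RAS-Cetux varied 0.85 → 0.89, the published ICER
decrease of $181,069.06/QALY does not follow from the published totals
(16,828.02/0.08 implies a decrease of $210,350.25). It is excluded from
reproduction targets and noted here.

## Synthetic data and what tests show

`generate_strategies()` draws strategy sets uniformly within configurable
ranges (medians 4–24 months PFS with 3–30 months post-progression offset,
costs on the order of the base-case regimens, utilities bracketing
0.85/0.65 — uniform draws are deliberate: the generator is test
scaffolding, not a scientific claim) and attaches closed-form expected
cost/QALYs plus the true frontier as ground truth. The generator
emulates exponential time-to-event structure summarised by medians,
decomposable cost schedules and utility-weighted occupancy; it does not
emulate patient-level heterogeneity, non-proportional hazards, or
correlated costs, so passing tests demonstrate the *arithmetic machinery*
is correct, not that real cohorts behave exponentially.

Problem sizes in the test suite and acceptance script: 100 synthetic
strategies for the engine-vs-closed-form check (tolerance 0.1%, observed
error at machine precision), 10,000 × 50 microsimulation draws, 2 × 10⁵
exponential samples for parameter recovery (within 2% for medians ≥ 6
months), 50-point bisection-oracle sweep for the median conversion.

## Known limitations

- Exponential (memoryless) survival throughout; real PFS/OS curves are
  not exponential, and the post-progression decomposition inherits the
  assumption.
- Unpublished cost cells are calibration inputs; engine-mode totals move
  with them. The published-totals surface is insulated from this.
- No dose reductions, vial wastage, BSA/weight distributions, or
  time-varying transition probabilities.
- The willingness-to-pay threshold ($20,301/QALY, triple per-capita GDP)
  and the 6.15 CNY/USD rate are fixed inputs of the study setting, not
  outputs.
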