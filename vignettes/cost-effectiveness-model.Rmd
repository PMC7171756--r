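---
title: "A partitioned-survival cost-effectiveness model for second-line cabozantinib in advanced HCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned-survival cost-effectiveness model for second-line cabozantinib in advanced HCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cabohce)
```

## The decision problem

Cabozantinib, a tyrosine kinase inhibitor, prolongs overall survival (OS,
median 10.2 vs 8.0 months) and progression-free survival (PFS, 5.2 vs 1.9
months) compared with placebo in sorafenib-pretreated advanced
hepatocellular carcinoma (HCC). Whether that gain is worth its price is a
question for a cost-utility model: this package implements a three-state
cohort model (stable → progressive → dead) that compares cabozantinib plus
best supportive care (BSC) against BSC alone under German
statutory-health-insurance prices and a US cash-price scenario.

## Model structure and assumptions

**Partitioned survival.** Only the published OS and PFS curves are
available — no patient-level data — so state occupancy is derived directly
from the two survival functions: `stable = S_PFS(t)`, `dead = 1 − S_OS(t)`,
`progressive` the difference. This reproduces exactly the transition
structure implied by the curves and is the standard approach when a Markov
model is parameterized from published Kaplan-Meier plots. An equivalent
per-cycle transition-probability view (`cycle_transition_prob()`, the
conditional-survival conversion `1 − S(t+Δ)/S(t)`) is exposed for
inspection. One consequence is that the stable→progressive versus
stable→dead split is not separately identified; nothing in the base case
needs it, and the one scenario that does (the progression rebate, below)
documents its convention.

**Curve crossing.** Independently extrapolated PFS and OS curves can cross
in the tail (S_PFS > S_OS). Occupancy is then clamped — progressive at 0,
the excess assigned to dead — with a warning. Row sums stay exactly 1; the
invariant is tested to 1e-12 every cycle.

**Cycles, horizon, discounting.** 84 monthly cycles (a lifetime horizon in
this palliative population: under the base-case curves under 0.5% of the
cohort remains alive at month 84), cycle length one month standing in for
the 30-day cycle. The discount factor `(1+r)^(−t/12)` with r = 3%/year is
applied at cycle start, and accrual uses cycle-start occupancy with no
half-cycle correction by default: monthly cost × discounted state-months
then reproduces the published breakdown arithmetic (e.g. drug total =
price × discounted stable months) exactly, which is how the cost-accrual
state mapping below was validated. A trapezoid half-cycle correction is
available as a settings switch.

**Cost accrual rules.** Drug and adverse-event costs accrue in stable
cycles only (therapy and its toxicity stop at progression); consultation,
laboratory and imaging accrue in all alive cycles; each category has a
first-cycle value and a possibly deviating subsequent-month value,
following the published cost table's bracket convention. One-off costs
(e.g. single hospitalizations per AE) are charged in cycle 1 of stable.
This mapping reproduces the published per-category totals to rounding when
fed the published discounted state-months.

## Survival fitting and selection

Five families — exponential, Weibull, Gompertz, log-logistic, lognormal —
in their conventional survival forms (e.g. Weibull `S = exp(−(t/λ)^γ)`,
Gompertz `S = exp((b/a)(1 − e^{at}))`) are fitted to digitized KM points by
least squares. Because the input is plot coordinates rather than
individual-level data, goodness of fit uses the Gaussian least-squares
information criteria `n·ln(SSR/n) + 2k` (AIC) and `+ k·ln(n)` (BIC); these
are the only forms that produce the characteristic negative values seen in
published SSR-based fit tables. Optimization is Nelder-Mead (Brent for
one-parameter families) from five deterministic median-anchored starts with
positive parameters log-transformed, which avoids boundary failures; a
50×50 grid-search oracle in the test suite verifies the optimizer is never
beaten. Gompertz shapes a ≤ 0 are excluded at validation: they leave a
plateau `S(∞) = exp(b/a) > 0`, i.e. an immortal fraction.

Selection ranks by SSR with AIC, BIC and finally a fixed family order as
deterministic tie-breaks. A plausibility flag marks winners whose hazard
vanishes at long times (log-logistic, lognormal): for an OS endpoint in a
palliative setting a hazard decaying to zero is clinically implausible, so
the flag turns into a warning there.

## The synthetic-data generator

`celestial_fixture()` builds the full input bundle offline: four Weibull
distributions with common shape 1.3 and scales solved in closed form from
the printed medians (10.2/8.0 months OS, 5.2/1.9 months PFS), the published
per-country monthly cost tables, utilities 0.76/0.68, GDP values and PPP
rates. Shape 1.3 is a choice, not an estimate — the authors' fitted shapes
are in an unavailable supplement — made once because it gives the
monotonically increasing hazard their fit table attributes to the selected
Weibull while matching every printed median exactly. `simulate_survival()`
draws event times by inverse-CDF sampling with uniform random plus
administrative censoring, the uniform bound calibrated by bisection to the
target censoring fraction (default 0.2, a modelling convenience; the
trial's censoring pattern is unpublished). Kaplan-Meier estimation uses the
survival package's product-limit estimator, cross-checked in the tests
against a hand enumeration oracle.

What the generator does *not* emulate: treatment crossover, dose
reductions, non-proportional censoring, and the authors' actual digitized
coordinates. Passing tests therefore demonstrate parameter recovery and
pipeline correctness under clean Weibull data, not that the fixture's
absolute ICERs equal the published ones — the published base-case numbers
are instead reproduced through their own printed inputs (state-level LYs,
per-arm totals) in the acceptance layer, and the fixture-driven run is
checked against structural facts (drug share > 90% of intervention-arm
cost, superior effectiveness in all PSA iterations).

## Scenario and sensitivity machinery

**Therapy cap.** Drug cost restricted to the first 4 stable cycles,
emulating the median time-to-discontinuation (3.8 months) being shorter
than median PFS.

**Progression rebate.** One monthly drug price credited per patient at
progression. In a cohort model there are no individuals, so the credit is
expectation-weighted: each cycle's mass newly leaving stable is credited
one monthly price, discounted at the entry cycle. Attributing all
stable-leavers to progression slightly overstates the credit (some die
without progressing); the alternative — ignoring deaths-from-stable
entirely — is not identifiable from two curves, and the scenario is a
bounding analysis in any case.

**Utility variants** replace the per-arm (stable, progressive) pairs with
published alternative sets; the decreasing-utility scenario subtracts
0.005 per month from the progressive utility. Because a cohort model
cannot track time-in-state without tunnel states, the decrement runs on
model time — a conservative approximation that slightly understates
progressive QALYs for late progressors.

**One-way analysis** sweeps each parameter to its bounds (default ±25% of
base where no range is stated, since the published intervals are shown
only graphically) and reports ICER bar widths sorted descending; drug
price and the stable utility dominate, as in the published tornado.

**PSA.** 10,000 iterations; gamma for costs (shape `(mean/se)²`, scale
`se²/mean`; se defaults to 20% of the mean — the published gamma
hyperparameters are supplement-only), scaled beta on [0, 0.05] with mean
3% for the discount rate (concentration α+β = 10, giving α = 6, β = 4),
truncated normal (resampling, se 0.05) for utilities. Survival-curve
uncertainty is not propagated, matching the stated scope of the published
PSA (costs, discounting, utilities). Acceptability is the fraction of
iterations with positive net monetary benefit λ·ΔE − ΔC > 0 — sign-safe
when an iteration's incremental effect is negative, unlike an ICER ≤ λ
rule. All draws are seed-deterministic.

## Numerical choices and degenerate inputs

- Occupancy conservation enforced to 1e-12; cost category totals sum to the
  grand total to 1e-9 (both tested).
- `SSR = 0` (perfect fit) returns −Inf information criteria with a warning
  rather than an error, so noiseless self-consistency checks rank first.
- A flat (all-equal-survival) curve is flagged degenerate; the exponential
  fit is reported at its rate→0 boundary.
- Survival underflow in the conditional-survival conversion returns
  transition probability 1 with a notice.
- The break-even price search is bisection to ±$1 on a monotone ICER;
  thresholds already met at list price, or never met at any price, return
  labelled statuses instead of a root.
- Monetary results are kept unrounded internally and rounded to whole
  dollars only at presentation; utilities to 3 decimals.

## Problem sizes

The test suite simulates cohorts of n = 500 (parameter recovery, ten
seeds), n = 2000–5000 (median checks), fits 20 random curves against the
grid oracle, and runs the full 10,000-iteration PSA once; the analysis
scripts use the same sizes. These match the scale of the published
analysis (10,000 PSA iterations) and keep a full run to a few minutes.

## Known limitations

- The published Table-1 SSR/AIC/BIC values cannot be reproduced without the
  authors' digitized coordinates; the fit layer is validated by parameter
  recovery and oracle bounds instead.
- Exact PSA probabilities depend on supplement-only distribution
  hyperparameters; the acceptability curve is validated structurally
  (monotone, correct limits) and qualitatively against the published
  pattern.
- The partitioned-survival identity assumes the extrapolated curves refer
  to the same cohort; crossing tails are clamped rather than re-modelled.
- No individual-level microsimulation, no time-to-discontinuation model
  beyond the two published scenarios, no budget-impact analysis.
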