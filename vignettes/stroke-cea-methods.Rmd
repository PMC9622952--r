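---
title: "Methods: a decision-tree/Markov cost-effectiveness model for neuroprotection in acute ischemic stroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stroke cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecea)
```

## The decision problem

Edaravone dexborneol, a combination neuroprotectant, improved the
proportion of acute ischemic stroke patients reaching a good 90-day
functional outcome (mRS 0–1) relative to edaravone alone in a large
randomized trial, at a substantially higher drug-course price. Whether the
short-term functional benefit justifies the price from the Chinese
healthcare system's perspective is a classic cost-utility question, and
the package answers it with the field's standard machinery: a short-term
decision tree fixing day-90 outcomes, a long-term Markov cohort model for
everything after, and deterministic plus probabilistic uncertainty
analysis.

## Model structure and assumptions

**Decision tree (day 0–90).** Each arm's day-90 mRS distribution is taken
directly from the trial (`default_parameters()$arms`). The acute phase
charges the full 14-day drug course, 28 intravenous injections, and a
one-time hospitalization cost by outcome class (mRS 0–1, mRS 2–5, dead);
day-90 deaths receive the dead-class hospitalization cost and the full
treatment cost. The published dexborneol row sums to 100.1 % because the
proportions are printed to 0.1 points; validation tolerates that residue
and `build_acute_outcome()` renormalizes before use.

**Markov model (annual cycles).** Survivors enter at age 63 and cycle for
up to 30 years through seven states: three post-stroke disability bands,
three single-cycle recurrent-stroke tunnel states and death. Tunnel states
exist so that the recurrence year can carry its own utility (0.34) and its
own event cost (28,987.05 CNY) instead of the band's annual values; all
tunnel occupancy leaves after one cycle. Competing risks within a cycle
are applied multiplicatively, recurrence first and then death; the
alternative order differs only at second order in the (small) event
probabilities. Recurrence survivors return to their pre-recurrence band by
default ("equal disability"); `recurrence_destination` accepts any
row-stochastic worsening matrix because the evidence only constrains the
destination to be of equal or greater severity.

**Background mortality.** The model multiplies an age-specific background
annual death probability by a disability-specific hazard ratio. Literal
multiplication can exceed 1 at high ages, so the default applies the ratio
on the hazard scale, \(1-(1-q)^{hr}\), which agrees with multiplication to
first order (within ~2 % over the model's working range) and is always a
valid probability; `mortality_hr_mode = "multiply_capped"` preserves the
literal reading.

**Valuation.** Per-cycle QALYs and maintenance costs use the average of
start- and end-of-cycle occupancy (half-cycle correction); recurrence
event costs are charged per tunnel occupancy without cycle-length scaling
because they are event costs, not time costs. Cycle 0 (the acute quarter)
contributes 0.25 years at day-90 utilities, undiscounted and uncorrected.
Under the default `first_cycle_mode = "fractional_075"` the first annual
cycle contributes 0.75 years so that cycle 0 plus cycle 1 complete the
first model year; `"full_year"` is available and is what the closed-form
test limit (total QALYs = 0.25 + horizon under zero
mortality/recurrence/discount with unit utilities) uses.

## Parameters, units and defaults

All inputs live in one validated object (`default_parameters()`), are
round-trippable through a commented YAML config
(`inst/extdata/default_parameters.yaml`), and carry the tabulated
base-case values: recurrence rate 0.12 per patient-year growing 1.019-fold
per life year, recurrent-stroke death probability 0.21, hazard ratios
1.00/1.19/2.04, costs in 2021 CNY, discount rate 5 %/year (admissible
range 0–8 %), WTP 121,464 CNY/QALY, entry age 63, horizon 30 years. Each
uncertain input also carries its plausible range and distribution family
for the sensitivity analyses.

### The two utility presets

The evidence base is internally inconsistent about utilities: the input
table prints 0.80/0.58/0.28 for mRS 0–1/2–3/4–5, while the accompanying
narrative (and back-calculation of the published 1-year QALY levels of
0.76 and 0.79) implies 0.84/0.78/0.36. Neither can be dismissed, so both
ship as named presets (`utility_presets`; `set_utility_preset()`), the
package never silently picks one, and every analysis records the preset in
its manifest. The presets matter: the narrow 0.84–0.78 spread of the
`"text"` set compresses the 1-year QALY increment (the intervention mostly
moves patients between mRS 0–1 and 2–3), while the `"table1"` spread
widens it; published QALY *levels* are only consistent with `"text"`,
published *increments* and the 1-year ICER only with `"table1"`. This is a
contradiction in the source, not a tunable of the model.

### Discount timing

The conventional formula divides cycle-\(t\) flows by \((1+r)^t\)
(`discount_timing = "end_of_cycle"`, the default). The published 1-year
QALY levels, however, equal the *undiscounted* day-90 expected utility,
showing the original spreadsheet left its first model year undiscounted;
`"start_of_cycle"` reproduces that by using \((1+r)^{-(t-1)}\). The
reproduction harness (`scripts/acceptance.R`) uses `"start_of_cycle"` and
says so.

## The synthetic life table

The one external input — age-specific background mortality from the
national statistical yearbook — is not printed in the evidence base, so
the package substitutes a synthetic Gompertz life table,
\(q_x = 1-\exp(-a e^{b x})\) with \(a = 2\times10^{-5}\), \(b = 0.085\)
(constants in the config, not the code), covering ages 63–93. It is
labelled synthetic in its filename and here: it reproduces the *shape* of
adult all-cause mortality but sits below the 2020 Chinese level (≈ 0.42 %
annual at 63 versus ≈ 1 % in the real table). That matters for one result
class: with weak background mortality the survival-cost component of the
long-horizon cost increment (extra years of care purchased by the
longevity gain) is suppressed, so the 30-year incremental cost — and with
it the 30-year ICER — comes out far smaller than published, while QALY
increments and the INMB (dominated by the QALY term) are barely affected.
Users with the real yearbook table can pass it via `read_life_table()` or
`--life-table`; the model itself is agnostic.

## Sensitivity analyses

**One-way.** `owsa()` sets each ranged parameter to its low and high value
with everything else at base and reports the INMB pair; the efficacy odds
ratio (CI 1.12–1.81) acts through the published transform
\(p_2 = OR\,p_1/(1+(OR-1)p_1)\) applied to the control arm's mRS 0–1
share, with the complement redistributed over the remaining states in the
intervention arm's base-case proportions.

**Probabilistic.** `run_psa()` draws both arms' day-90 distributions from
Dirichlet posteriors with concentration = proportions × 600 (the per-arm
trial size; the alternative control-Dirichlet + odds-ratio-draw mode is
`psa_efficacy_mode = "or"`). Ranges are read as central 95 % intervals and
moment-matched: beta and gamma match mean and sd = range/3.92, lognormal
takes the base as median and the range as a ratio-scale 95 % interval.
Utility draws violating the severity ordering are rejected and redrawn
(counted in the result). Everything is reproducible bit-for-bit given the
seed.

## Numerical choices and degenerate inputs

Rates become probabilities by the exponential transform \(1-e^{-r}\)
(`rate_to_prob = "literal"` preserves the naive reading). Transition-matrix
rows are asserted to sum to 1 within \(10^{-9}\) on every build; cohort
occupancy is conserved to the same tolerance. Zero-width sensitivity
ranges collapse to point masses; a base value outside its printed range
(the evidence prints one such cost range) is moment-matched as-is with a
warning. Degenerate requests fail loudly: recurrence rates ≥ 5/year,
Gompertz parameters driving \(q \ge 1\), horizons beyond the life table.

## Problem sizes and verification

The test-suite exercises the full 30-year model (milliseconds per run), a
5,000-iteration PSA (tens of seconds), a 100,000-individual
microsimulation oracle that re-derives the cohort trace by direct
sampling, 1,000-draw ICER/INMB consistency checks, and 50 perturbed
parameter sets from the synthetic-data generator (mean-preserving
multiplicative noise on positive inputs, logit-scale noise on
probabilities, resampling on invariant violation). The microsimulation and
the closed-form QALY limit are the two fixture-independent oracles: they
validate the engine, not the fixture.

## Known limitations

- The synthetic life table understates Chinese background mortality (see
  above); absolute long-horizon costs and the 30-year ICER inherit that.
- The utility contradiction in the source cannot be resolved by the
  package, only made explicit.
- No adverse-event, societal or indirect costs; no NIHSS or sex strata;
  recurrence severity distribution is not band-specific.
- Recurrence risk does not depend on the number of prior recurrences.
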