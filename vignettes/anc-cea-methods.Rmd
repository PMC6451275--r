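---
title: "Methods: cost-effectiveness of an eight-contact ANC schedule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-effectiveness of an eight-contact ANC schedule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anccea)
```

`anccea` estimates the incremental cost per life-year saved (LYS) of moving
from a four-visit antenatal care (ANC) schedule to the 2016 WHO eight-contact
schedule, over a one-year implementation period and from the societal
perspective, parameterised for Rwanda. This vignette is the package's account
of the model: what is assumed, which knobs matter, the numerical conventions,
and what the shipped tests do and do not demonstrate.

## Model structure

The analysis has four independent stages, crossed at the end:

1. **Attendance**: how many ANC visits each of 373,679 women attends under a
   policy scenario — a normal distribution of visit counts, discretised and
   clipped (`attendance_scenario()`, `draw_visit_counts()`).
2. **Costing**: a woman attending `k` visits is costed as the sum of the unit
   costs of scheduled visits `1..k` (`cumulative_cost()`); national totals
   are averaged over 100 Monte Carlo replications
   (`simulate_cost_distribution()`).
3. **Health outcomes**: optimistic and pessimistic mortality-reduction
   scenarios from a two-round expert panel (`merge_delphi_rounds()`,
   `build_outcome_scenarios()`), converted to deaths averted and discounted
   LYS (`health_gains()`).
4. **Cost-effectiveness**: every costing x outcome cell gets an ICER and a
   GDP-threshold classification (`build_cea_table()`).

Attendance and effectiveness are treated as independent: there is no
evidence base for a joint model, so all six combinations are reported, even
pairings one might judge unlikely (high attendance with pessimistic
outcomes). The costing convention — attending `k` visits delivers the content
of visits `1..k` in order — is a deliberate simplification; in reality a
woman presenting late receives late-schedule content first.

## Key parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| unit costs, four-visit | 21, 6, 6, 11 | 2015 USD | micro-costed current practice |
| unit costs, eight-contact | 24, 6, 10, 6, 6, 10, 6, 11 | 2015 USD | current costs + $3 ultrasound (visit 1) + $3.75 repeat tests (visits 3, 6, printed as 10) |
| `overflow_visit_cost` | 6 | USD | visits 9–11 carry no scheduled tests, so they are priced as ordinary routine visits |
| attendance means (scenarios 1–3) | 5, 6, 7 | visits | conservative to ambitious uptake of the new schedule |
| attendance ranges | [1,8], [2,10], [3,11] | visits | scenario definitions |
| `sd_visits` | 0.8 | visits | carried over from the observed current-practice distribution (mean 3.3, median 3, SD 0.8); reproduces the reported per-woman means, SDs and observed extremes |
| `n_replications` | 100 | — | replication design of the original simulation |
| baseline deaths | 10,076 perinatal, 371 maternal | deaths/year | 2015 national health statistics |
| life expectancy | 64 (both sexes), 66 (female) | years | 2012 census |
| `discount_rate` | 0.03 | per year | standard practice for health gains |
| `gdp_per_capita` | 697 | 2015 USD | threshold anchor; 1x / 3x multipliers |
| comparator cost | 13,939,970 total; 37/woman | 2015 USD | current practice, taken as a fixed input (it comes from primary micro-costing, not from this simulation) |

## Numerical conventions

* **Discretisation**: continuous normal draws are rounded half away from
  zero, then clipped to the scenario range. The closed-form oracle
  (`expected_cost_closed_form()`) uses the matching probability mass
  function, `pnorm(k + 0.5) - pnorm(k - 0.5)` with tail mass folded into the
  bounds. Note that discretisation inflates the standard deviation of counts
  slightly (for the current-practice survey, the exact discretised SD is
  0.850 against the underlying 0.8); tests therefore compare sample moments
  against the exact discretised moments, not the continuous parameter.
* **Rounding**: deaths averted are rounded half up to whole deaths; ICERs
  are reported half-up to whole dollars; LYS are carried at full precision
  and rounded only in reports. Monetary amounts are plain doubles — every
  unit cost is a whole dollar and the only sub-dollar input (the $0.75
  repeat test, already folded into the printed $10) is dyadic, so all sums
  are exact in binary floating point.
* **Seeding**: every stochastic function takes an explicit seed.
  `simulate_cost_distribution()` derives one sub-seed per replication and
  `run_pipeline()` one per scenario from the master seed, so results are
  independent of execution order and byte-identical across reruns;
  `results.json` contains no timestamps for the same reason.
* **Discounting**: the formula was an open choice; the package uses the
  standard end-of-year annuity `A(n, r) = (1 - (1 + r)^-n)/r` over an
  integer horizon, which reduces to `n` at `r = 0`.

## The perinatal discounting horizon: two variants

The methods convention assigns a perinatal death the both-sexes life
expectancy at birth, 64 years. The reference tabulations this package is
designed to reproduce, however, imply a 66-year horizon: their perinatal LYS
divided by deaths averted equals `A(66, 0.03) = 28.595` to three decimals
(and their two perinatal cells imply factors differing in the third decimal,
so no single horizon reproduces both exactly). Both conventions are shipped:

* `rwanda_anc_inputs("replication")` — horizon 66, matches the reference LYS
  tables to within 0.1% (the default, used by the acceptance checks);
* `rwanda_anc_inputs("nominal")` — horizon 64, the stated convention.

Reports label the active variant in their manifest.

## Maternal age-at-death distribution

Maternal LYS weight each averted death by the discounted remaining female
life expectancy at the age of death. The original age shares are not
available, so the package ships a synthetic DHS-style distribution: 5-year
age groups with midpoints 17.5–47.5 and a plausible base share vector,
calibrated by `calibrate_age_shares()` — a closed-form one-parameter mixture
with a point mass on the oldest group — so that the implied discounted years
per maternal death equals 4044/195 = 20.7385, the ratio of two reference
cells (optimistic maternal LYS over deaths averted). Only this aggregate
factor is identifiable from the published material; the shares themselves
are a labelled synthetic stand-in.

## Expert-panel conventions

Round-2 responses supersede round-1; non-response in round 2 confirms the
round-1 estimate. Scenario construction sorts each indicator independently
(an expert can be optimistic about perinatal and pessimistic about maternal
mortality), splits at the median, and takes sub-group means. Two edge
conventions the source material leaves open, fixed here and configurable:
for an odd panel the middle value joins the lower (pessimistic) half — the
conservative choice — and boundary ties are resolved by a stable sort so
results are deterministic. Reductions are stored as positive percentages;
the mortality-decrease sign is applied at reporting time.

## Known input inconsistencies

Two internal inconsistencies in the reference figures are handled by
flagging, not by matching:

* **Scenario 3**: the published total (24,895,023) contradicts the published
  per-woman mean (69 x 373,679 ≈ 25.8M). The simulation reproduces the
  per-woman mean; `run_pipeline()` flags the scenario-3 total (and any total
  deviating >1% from a configured published figure) in the cost table. Its
  derived quantities — the 79% cost increase and the $67/$168 ICER column —
  are likewise not matched by the consistent simulation, which yields ≈86%
  and $73/$182.
* **Replication spread**: the claimed min–max spread of "0.001% and below"
  across 100 replications is inconsistent with the published min/max totals,
  which imply ≈0.09%. `relative_spread_check()` defaults to a 0.2%
  threshold, which the simulation satisfies with margin.

The comparator for *per-woman* incremental cost is also ambiguous in the
source (its printed values subtract the $44 full-compliance cost, while the
total column subtracts the $13.94M current-practice total); the cost table
reports both columns.

## Synthetic data: what it does and does not emulate

`generate_attendance_survey()` emulates a household attendance survey as a
discretised clipped normal — adequate for the moments and median that drive
the costing, but real attendance data are right-skewed counts with
heaping, and no woman-level covariates are modelled.
`generate_expert_panel()` builds panels by inverse design (half-means fixed
first, members jittered within halves), so elicitation targets are recovered
exactly by construction; it emulates the bookkeeping of a two-round Delphi
(revision, confirmation, non-response), not expert psychology — anchoring,
overconfidence and correlated opinions are out of scope. Passing tests
therefore demonstrate that the pipeline is correct and internally
consistent, not that the elicited effect sizes are externally valid.

## Problem sizes

The full replication — three costing scenarios x 100 replications x 373,679
women (≈112M draws) — runs in seconds vectorised, and is what
`test-acceptance.R` and `scripts/acceptance.R` execute. Unit and property
tests use smaller cohorts (3,000–50,000) and replication counts (3–20),
sized so that Monte Carlo error bounds (3 standard errors) are still sharp
enough to detect implementation mistakes.

## Limitations

Morbidity, quality-of-life and DALY outcomes are out of scope, as are
one-off implementation costs (ultrasound machines, training), visit-timing
effects, dependence between a woman's attendance and her mortality risk,
and probabilistic sensitivity analysis beyond the replication spread. The
GDP-threshold rule is phrased per DALY averted but applied here to LYS, a
documented equivalence assumption.
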