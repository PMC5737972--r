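---
title: "Evaluating a phased screening rollout on a Lexis grid: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a phased screening rollout on a Lexis grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenlexis)
```

## The design

`screenlexis` analyses a two-region, staggered rollout of an organised
mammography-screening programme as a quasi-experiment. The unit of
analysis is the 1-year × 1-year Lexis cell `(a, y)`: completed age `a` at
the start of calendar year `y`, with birth cohorts running along the
diagonals `c = y − a`. Two principles drive everything else:

1. **Incidence-based mortality.** A death may only count if the underlying
   cancer was diagnosed after the programme window opened (year ≥ 2000)
   and at an age the programme could reach (diagnosis age ≥ 50). Deaths
   from pre-programme diagnoses say nothing about screening and their
   inclusion biases the contrast toward the null.
2. **Matching over modelling for the headline estimate.** The mortality
   contrast is a Mantel–Haenszel summary over individual cells — exact
   age-and-year matching — rather than a regression adjustment. Regression
   enters only where a time course is wanted (band trends, the net-deficit
   model).

Cells split into a screening-**eligible** polygon (cohorts aged at most 64
in the reference year 2000) and a **too-old** polygon (65 or older in
2000). On the default 36-age × 14-year grid this is 301 + 203 = 504 cells.
The eligible-polygon rate ratio mixes the screening effect with any
inherent regional difference; the too-old polygon measures that background
difference alone; their ratio — the double difference — isolates the net
effect of earlier screening. Its log variance is the sum of the two
Breslow–Day variances, which the Woolf-like form
`1/D₁ + 1/D₀ + 1/D₁′ + 1/D₀′` approximates well; the smallest of the four
death totals dominates the interval width.

## The conditional-Poisson net-deficit model

Stage 2–4 incidence is the leading indicator of later mortality
reductions. Treating each cell's two region counts as independent Poissons
and conditioning on their total `n`, the region-1 count is binomial with

```
logit p(a, y) = log(T₁/T₀) + β_bg + b₀ + b₁·yc + b₂·yc²
```

where `T₁/T₀` is the person-time ratio (a fixed offset), `β_bg` the
background log rate ratio, and `exp(b₀ + b₁·yc + b₂·yc²)` the net rate
ratio `netRR(y)`; `1 − netRR(y)` is the fraction of the cancers that would
have surfaced at stage 2–4 in year `y` already removed by earlier
screening. Design choices:

* **Two-step background.** `β_bg` is estimated first from the too-old
  cells (constant-only fit) and plugged in as a fixed offset, not jointly
  estimated. This keeps the background identified purely by cells
  screening cannot touch; the cost is that its sampling error is not
  propagated into the net-coefficient standard errors.
* **Year centring.** `yc` is calendar year centred at the study midpoint
  (2006.5 by default) before polynomial expansion. The fit is invariant to
  relabelling years (tested); centring just conditions the Hessian.
* **Optimisation.** The analytic log-likelihood and gradient are maximised
  by BFGS with a relative-tolerance stop of 1e-12 (tighter than the 1e-9
  design target); the observed information from the numerical Hessian
  supplies standard errors. An IRLS logistic fit of the identical
  likelihood is used as an independent cross-check in the test suite, and
  the two agree to ~1e-9 on simulated grids.
* **Degenerate inputs.** Cells with zero total events carry no likelihood
  and are dropped; cells with events but one-sided person-time are an
  error; complete separation (all events in one region) is an error rather
  than a divergent fit.

The MH machinery makes the corresponding choices: strata with no
person-time are skipped silently (but counted); strata with events but
person-time on one side only are dropped with a warning; a zero weighted
denominator is an error. All intervals are 95% with z = 1.96 fixed.
Displayed ratios are rounded to two decimals in print methods only — stored
values are never rounded.

## Grid geometry decisions

Several conventions were genuinely open and are fixed as follows:

* **Whole-year clock.** A programme starting in February 2000 is treated
  as first round year 2000; one starting in December 2007 as first round
  year 2008. With 1-year cells a December start contributes negligible
  exposure to its nominal year.
* **Cohort entry.** A cohort younger than 50 at programme start is first
  invited in the calendar year it turns 50 and follows its own biennial
  clock thereafter. Under the default early-region schedule this yields a
  maximum of 7 invitations over 2000–2013, with every fully covered
  cohort reaching it.
* **The oldest age row.** The grid runs to age 85 (36 ages) — required to
  reproduce the 301/203 polygon split — but deaths are counted only at
  ages 50–84 by default (`death_age_range`), so the age-85 row carries
  person-time only. Both windows are arguments, not constants.
* **Smoothing at edges.** The 3×3 display smoother uses truncated-window
  means: edge and corner cells average the 6 or 4 cells that exist.
  Padding would invent data outside the grid; truncation keeps every
  output inside the input range and the smoother idempotent on constants.
* **Trend bands.** The seven default bands over 2000–2007 are three
  5-year attained-age bands (120 cells) and four 5-cohort diagonal bands.
  Diagonal membership is "cells the cohort traverses inside the grid",
  which gives 25 + 40 + 40 + 40 = 145 cells and leaves exactly the 3 cells
  of the cohorts reaching age 50 in 2006–07 unassigned. Band bounds are
  configurable.

## What the simulator emulates — and what it does not

`simulate_registry()` is a per-woman microsimulation: each woman follows
her cohort diagonal from 2000; each year she may be clinically diagnosed
(age-dependent hazard); stage at clinical diagnosis is 2–4 with a fixed
probability; a *participating* woman (a latent per-woman trait, P = 0.70 —
matching the 100/70 deattenuation logic, not re-drawn per round) who is
invited in year `r` has any clinical diagnosis within her lead time after
`r` advanced to `r`, where it is recorded stage 1 with the stage-shift
probability; survival after the *recorded* diagnosis is geometric with a
stage-specific per-year hazard. Person-time accrues through the death year
inclusive.

Default parameters (each an explicit `sim_config()` argument):

| parameter | default | rationale |
|---|---|---|
| cohort size | 6,000 / cohort / region | ≈ 300k women aged 50–85 per region, the scale of the motivating setting |
| clinical hazard | 2.4e-3 + 2e-5·(age−50) per WY | incidence ≈ 240–310 per 100k at ages 50–85 |
| stage 2–4 fraction | 0.55 | pre-screening case mix |
| participation | 0.70 | programme uptake of ~68–76% |
| lead time | Poisson, mean 2 y | sojourn consistent with a biennial interval |
| stage shift | 0.50 | screen-detected advanced cases recorded early |
| case fatality | 0.015 / 0.08 per year | stage-1 vs stage-2–4 annual death hazards |
| other-cause mortality | off | contrasts condition on supplied person-time |

These are *illustrative*, chosen once to land in realistic ranges; no
parameter encodes a target estimate, and the net effects in the microsim
are emergent. The mechanism reproduces the signature time pattern
(verified on exact expected surfaces, not noisy draws): a prevalence-round
*excess* of stage 2–4 cases in the early-screened region, a sustained
deficit until the second region starts, then convergence; and mortality
benefits that appear only after a region's first invitation round.

What it does **not** emulate: tumour natural history (growth,
sojourn-by-grade), overdiagnosis, inter-round interval cancers as a
distinct biology (they arise only via short lead-time draws), migration,
county-level geography, or registry ascertainment error. Passing tests
therefore show the *estimators* behave correctly under the assumed
structure — not that the structure captures everything in real registry
data. Diagnoses that would surface after the follow-up end are never
generated, so screen-detection near the window boundary is slightly
understated in both the simulator and its expectation oracle,
consistently.

`expected_cell_rates()` computes the exact per-cell expectations of the
same mechanism by summing over the lead-time distribution (upper tail
lumped where detection saturates, which is exact) and the geometric
survival. It is the simulator's analytic oracle: simulated totals at ~1e5
women sit within 3 standard errors of it in the test suite, and the
participation mixture identity
`E[p] = p·E[participation = 1] + (1−p)·E[participation = 0]`
holds to machine precision.

Because the microsimulation's net effect is emergent, a *second*,
deliberately simple generator (`simulate_rate_registry()`,
`simulate_stage24_grid()`) draws cell counts directly from Poisson rates
in which the background and net ratios are explicit parameters. That is
the right tool for operating-characteristic studies with a known truth:
the test suite runs 500 replicate registries at a true net mortality ratio
of 0.85 with person-time shaped like the study (~2.9/2.7 million
women-years eligible, ~0.9 million too-old, roughly a thousand eligible
deaths per arm) and checks 95% interval coverage and bias, plus a
100-replicate quadratic-deficit recovery of the conditional-Poisson
coefficients. Those problem sizes are the package's calibration-study
design; the remaining tests use small grids.

## Worked pipeline

```{r pipeline}
report <- run_pipeline(list(sim = list(cohort_size = 1000L), seed = 1))
report
round(100 * (1 - unlist(report$net_model$net_ratio)), 1)  # deficit by year
```

## Known limitations

* Two regions only; multi-phase rollouts (e.g. counties joining mid-way)
  must be collapsed or excluded upstream, as the motivating design did
  with its 2004–06 counties.
* The background offset is plugged in, so net-model intervals are slightly
  anti-conservative when too-old events are few.
* No overdispersion: the conditional-Poisson model inherits the Poisson
  assumption within cells; extra-Poisson variation would narrow nominal
  intervals.
* Exact (conditional) intervals and continuity corrections are out of
  scope; all intervals are Wald-type on the log scale.
* Person-time is taken from the supplied denominator table as-is; the
  package does not reconstruct population denominators from census data.
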