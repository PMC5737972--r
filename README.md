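# screenlexis

Quasi-experimental evaluation of phased cancer-screening rollouts on a
Lexis grid, in R.

## The problem

When a mammography-screening programme is rolled out region by region, the
late-starting region is a contemporaneous control for the early one. A fair
mortality comparison must be *incidence-based*: it may only count deaths
from cancers diagnosed **after** the programme began, at ages the programme
could reach — otherwise deaths in women who could never have benefitted
dilute the contrast. `screenlexis` implements that design for two regions
with staggered starts (by default: biennial invitations at ages 50–64,
starting 2000 in region 1 and 2008 in region 2, follow-up through 2013),
for epidemiologists and registry analysts who want the whole pipeline —
tabulation, matching, estimation, and a validating simulator — as tested,
reusable code.

## The estimators

Everything lives on a 36 age × 14 year Lexis grid whose cells `(a, y)`
split into a screening-**eligible** polygon (cohorts aged ≤ 64 in 2000;
301 cells) and a **too-old** polygon (aged ≥ 65 in 2000; 203 cells).

- **Mantel–Haenszel rate ratio**, one stratum per cell:
  `RR = Σ d₁ᵢt₀ᵢ/tᵢ ÷ Σ d₀ᵢt₁ᵢ/tᵢ`, with the Breslow–Day person-time
  variance for `log RR` (≈ `1/D₁ + 1/D₀` when person-time is balanced).
- **Double difference**: `netRR = RR_eligible / RR_background`. The
  background ratio from the too-old polygon absorbs inherent regional
  differences; what remains is attributable to earlier screening. Its log
  variance is the sum of the component variances, well approximated by the
  Woolf-like form `1/D₁ + 1/D₀ + 1/D₁′ + 1/D₀′`. The percent reduction
  `100·(1 − netRR)` converts to deaths averted (scaled by the reference
  arm's deaths) and, divided by the participation fraction (0.70), to a
  full-participation efficacy.
- **Stage 2–4 incidence** as a leading indicator: Poisson annual-change
  fits in 5-year attained-age and birth-cohort bands, 14 year-specific
  age-matched MH ratios, and a **conditional-Poisson** model — fixing each
  cell's total stage 2–4 count, the region-1 share is binomial with
  `logit p = log(T₁/T₀) + β_bg + b₀ + b₁·yc + b₂·yc²`,
  so `1 − netRR(y)` traces the fraction of that year's stage 2–4 "target"
  already removed by earlier screening.

A microsimulation (`simulate_registry()`) generates registry records with
the assumed structure — biennial invitations, 70% fixed participation,
Poisson lead time, stage shift to stage 1, stage-dependent case fatality —
and `expected_cell_rates()` gives its exact per-cell expectations, so every
stage of the analysis is testable without confidential registry data.

## Worked example

```r
library(screenlexis)
cfg  <- sim_config(cohort_size = 3000L)      # synthetic two-region registry
sim  <- simulate_registry(cfg, seed = 1)
grid <- build_lexis_grid(sim$records, sim$women_years, cfg$spec)
part <- partition_cells(cfg$spec, cutoff = 64)

rr_eligible   <- region_contrast(grid, part, "eligible", "deaths")
rr_background <- region_contrast(grid, part, "too_old",  "deaths")
double_difference(rr_eligible, rr_background, participation = 0.70)
#> Double difference (net effect of earlier screening)
#>   net rate ratio:    0.84  (95% CI 0.70 to 1.01)
#>   percent reduction: 16%  (95% CI -1% to 30%)
#>   deaths averted:    99
#>   efficacy at full participation (70% uptake): 23%

netfit(grid, part, basis = "quadratic")
#> Net stage 2-4 deficit model (conditional Poisson, quadratic-in-time)
#>   background log rate ratio (offset): 0.0085
#>   coefficients (year centred at 2006.5):
#> (Intercept)      year_c     year_c2
#>    -0.44856     0.01973     0.01034
#>   fitted net deficit 1 - netRR(y): -12.4% to 36.6% across 2000-2013
```

The double difference says breast-cancer mortality in cohorts that could
benefit was 16% lower in the earlier-screened region than its counterfactual
(after background correction), ~99 deaths averted in this synthetic
population; deattenuated by 70% uptake, a 23% reduction among full
participants. The net-deficit model shows the stage 2–4 time course: an
early *excess* (the first screening rounds harvest cases that would have
surfaced later) turning into a sustained deficit, then narrowing once the
second region's programme starts.

`run_pipeline()` chains all stages (simulate/load → tabulate → partition →
contrasts → trends → net model) from a config list or YAML file — see
`inst/extdata/demo_pipeline.yaml` — and `inst/scripts/screenlexis` exposes
the same stages as shell subcommands (`simulate`, `tabulate`, `partition`,
`contrast`, `trends`, `netfit`, `run-all`).

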