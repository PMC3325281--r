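---
title: "Methods: a Markov cohort model for first-line glioblastoma strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for first-line glioblastoma strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmcea)
```

## The decision problem

Newly diagnosed glioblastoma patients, after maximal safe surgery, receive
radiotherapy alone (RT), radiotherapy plus nitrosourea chemotherapy (RT+NT,
nimustine/ACNU in Chinese practice) or radiotherapy plus temozolomide
(RT+TMZ). Temozolomide extends progression-free and overall survival but at
a drug cost that dominates the whole treatment episode. The model estimates
five-year direct medical costs and quality-adjusted life-years (QALYs) per
strategy — overall and in eight prognostic subgroups (MGMT methylation,
extent of surgery, age band) — and summarizes them as incremental
cost-effectiveness ratios (ICERs) against willingness-to-pay (WTP)
thresholds of \$11,034 and \$38,376 per QALY (three times the per-capita
GDP of China and of Shanghai). Indirect (societal) costs are out of scope;
so is any parametric family other than the Weibull.

## Model structure and assumptions

Three mutually exclusive states — disease-free, progressed, dead — with
one-month cycles over a 60-cycle horizon and no discounting (configurable).
Occupancies are obtained by **partitioned survival** rather than an explicit
transition matrix: `pf(t) = S_PFS(t)`, `dead(t) = 1 − S_OS(t)`,
`prog(t) = S_OS(t) − S_PFS(t)` clamped at zero. This reproduces both input
curves exactly and needs nothing beyond the two survivor functions. The
price is that direct disease-free→death transitions are not separately
identified: everyone leaving the disease-free state is counted as a
progression entrant (`new_prog`). That convention only matters for the
progressed-state utility tunnel, where it slightly over-assigns entrants;
with monthly cycles the effect is small. Imputed subgroup PFS curves can
cross the OS curve numerically; crossings beyond a 0.02 tolerance warn and
are clamped rather than rejected.

Costs and QALYs accrue over cycles 0..H−1 using start-of-cycle occupancies
with no half-cycle correction (a flag exists); with monthly cycles the
correction is well under the precision of the inputs.

## Weibull survival models

All survival uses the rate parameterization `S(t) = exp(−λ t^k)` with time
in months, so the hazard is `λ k t^(k−1)` and multiplying λ by a hazard
ratio multiplies the hazard by the same factor at all times. Tables whose
"scale" is a characteristic life are converted on input
(`parameterization = "characteristic_life"`), because published parameter
tables are ambiguous on this point surprisingly often.

`fit_weibull_km()` fits the complementary-log-log linearization
`ln(−ln S) = ln λ + k ln t` to Kaplan–Meier coordinates by least squares —
deterministic, reproducible, and exact on true-Weibull points. When at-risk
counts accompany the curve, the regression is iteratively reweighted with
delta-method precision weights `(S ln S)² n_risk` evaluated on the fitted
curve (two passes). The reweighting exists because the KM tail — few
subjects at risk — is extremely noisy after the cloglog transform and
otherwise induces a finite-sample bias of several percent in λ; with it,
the round-trip bias at n = 500 is under 2% (the test suite checks the
simulate → KM → fit loop at 20 seeds). Maximum likelihood on pseudo
individual-patient data (via `flexsurv`) serves as an independent
cross-check in the tests, not as the default method.

### Indirect comparison

No head-to-head trials cover all three strategies, so the RT+NT arm is
derived from RT under proportional hazards with a shared shape:
`λ_NT = HR × λ_RT`. The meta-analytic nitrosourea HR is not printed in the
base-case sources as a number usable here; the default 0.85 (95% CI
0.78–0.91) is the published meta-analysis OS hazard ratio for
nitrosourea+RT versus RT, applied to both endpoints and exposed in the
configuration (`hr_nt`).

### Subgroup PFS imputation

Several subgroups report OS but not PFS. The imputation assumes the
cycle-wise hazard-rate ratio `r(t) = h_PFS(t)/h_OS(t)` of the overall
cohort also holds in each subgroup: compute `r(t)` on the integer-month
grid 1..60 (month *ends*; t = 0 is excluded because `t^(k−1)` is singular
there for k < 1 — the grid position is configurable via the horizon but the
end-of-cycle choice is deliberate and matches the per-cycle reading of the
hazards), multiply by the subgroup OS hazard, and refit a Weibull hazard by
least squares on `ln h(t)`. The fit is exact for true-Weibull series; in
particular, when all inputs share a shape the closed form
`λ_sub,PFS = λ_sub,OS × λ_ov,PFS / λ_ov,OS` is recovered to rounding error,
and the identity case (subgroup = overall) returns the overall PFS exactly.
Standard errors for imputed parameters come from the log-hazard regression
and are flagged approximate.

## Costing

Unit costs (2009 USD, CNY converted at 6.50) are the shipped
`inst/extdata/costs.yaml`. Schedule conventions, where the source schedule
descriptions leave the cycle mapping open, are fixed as follows and
documented in `strategy_schedule()`:

- Radiotherapy 60 Gy / 2 Gy fractions, 5 days/week over 6 weeks → 20
  fractions in cycle 0, 10 in cycle 1.
- Concomitant TMZ 75 mg/m² daily for the 42 radiotherapy days → 30 doses in
  cycle 0, 12 in cycle 1; cycle 2 off; adjuvant cycles 3–8 of 5 days at
  150 mg/m² (first) then 200 mg/m² — the standard regimen consistent with
  the quoted 150–200 mg/m² range.
- Chemotherapy (and its expected adverse-event cost) is received by the
  disease-free fraction only and stops at progression; ACNU 100 mg/m²
  every 6 weeks is prorated ×30/42 per month while disease-free.
- **Capsule dosing**: prescribed milligrams map to 100 mg + 20 mg capsules.
  The package's costing default *rounds the dose up* to the next achievable
  20 mg multiple and prices the cheapest composition — capsules cannot be
  split and wastage-conservative rounding is the standard costing
  assumption; `tmz_daily_cost()` also offers `"nearest"` (ties up) and
  `"exact"` pro-rata conventions.
- **Initial surgery is not charged** by default: the cohort enters the
  model after surgery, and the operation/biopsy unit costs are used for
  second-line re-operation. A flag (`include_initial_surgery`) restores an
  upfront one-off weighted by the surgery mix. Charging it would add about
  \$4,500 to every strategy, which the five-year totals of the reference
  analysis clearly do not contain.
- **Follow-up** (\$90, MRI-dominated) is charged to every disease-free
  cycle by default (`follow_up_policy = "all_pf"`): MRI surveillance
  continues through adjuvant treatment in routine practice. The
  post-treatment-only alternative is available.
- Second line at progression: a configurable mix (default chemotherapy
  0.40, re-operation 0.10, best supportive care 0.50 — placeholder values,
  *not* sourced from the trials, exposed in `second_line_mix`). PCV drug
  cost \$125 per 8-week cycle is prorated ×30/56 monthly and capped at six
  PCV cycles per progressor, tracked by progression entry cohort;
  re-operation is a one-off at entry; supportive care \$735 per month.
- SAE management: expected cost = Σ probability × unit cost spread over the
  chemotherapy cycles, chemotherapy strategies only. Default incidence
  probabilities (hematologic 0.12, infection 0.03, gastrointestinal 0.03)
  are placeholders flagged in the configuration.

Total cost is linear in unit prices, non-negative, and undiscounted by
default.

## Utilities and QALYs

Disease-free utility is phase-dependent: the combined
radiotherapy(+chemotherapy) value in cycles 0–1, the adjuvant value during
adjuvant cycles (cycles 3–8 for TMZ; for NT every disease-free cycle from
cycle 2 on, because ACNU continues until progression — the
"while-treatment-continues" reading of the adjuvant state), and the
untreated disease-free value otherwise. The progressed state starts at
0.7314 and loses 0.02 per month spent in state, floored at zero. Because a
cohort trace does not track individuals, time in state is handled with
entry-cohort (tunnel) accounting: progression entrants are recorded per
cycle, deaths deplete all entry cohorts proportionally (the simplest
assumption consistent with a cohort model), and the state utility at a
cycle is the entrant-weighted mean of the decremented utilities. QALYs are
the occupancy-weighted utilities summed over cycles, divided by 12.

## Decision analysis

`incremental()` returns ΔC, ΔE and the ICER (flagged undefined at ΔE = 0).
`frontier()` classifies strict dominance (costlier, no more effective;
equal-QALY ties keep the cheaper strategy) and extended dominance (removal
until frontier ICERs strictly increase), verified in the tests against a
brute-force convex-combination oracle. ICERs are reported from unrounded
model outputs; the small discrepancy between an ICER computed from rounded
table cells and one computed from unrounded QALYs is a display artifact and
is documented where it arises. Net health benefit `ΔE − ΔC/WTP` is used for
tornado reporting; net monetary benefit `E·WTP − C` for acceptability-curve
argmaxes — the two orderings are equivalent at a fixed WTP.

## Uncertainty analysis

Distribution assignments: lognormal for costs, beta for utilities,
probabilities and proportions, bivariate normal for each Weibull
(shape, scale) pair. Ranges are read as central 95% intervals — the
`(low, high)` → variance convention is
`sd = (high − low)/(2 × 1.96)` (on the log scale for lognormal, with the
log-mean adjusted to preserve the arithmetic mean). This convention is a
modelling choice; a uniform-over-range alternative would widen nothing by
more than the ranges themselves. Degenerate items (low = high) collapse to
their mean, and a fully degenerate specification reproduces the base case
exactly — a property the tests rely on.

The PSA (default 1,000 draws) resamples every parameter, rebuilds the
survival models — re-running the subgroup imputation and hazard-ratio
scaling per draw — and re-evaluates all strategies. Invalid (non-positive)
Weibull draws are resampled and counted; independently drawn PFS/OS pairs
may cross, which the trace clamps (counted, not warned per draw). Second-line
proportions are drawn per component and renormalized to sum to one. CEAC
probabilities split ties equally and sum to one at every threshold; the
default WTP grid is \$1,000–\$120,000 in \$1,000 steps (zero is excluded
since WTP must be positive), spanning both reference thresholds. The
cost-effectiveness-plane ellipse uses the sample mean and covariance of
(ΔE, ΔC) with the chi-square(2 df) 0.95 radius.

One-way analysis re-runs the deterministic model at each parameter's range
ends; the tornado covers every cost, utility, the body surface area
(1.61–1.83 m²), the nitrosourea hazard ratios, SAE probabilities, and the
overall-cohort Weibull scales at ±1.96 SE. With the shipped configuration
the widest bar is the temozolomide 100 mg price, as expected when one drug
accounts for most of the incremental cost.

## Synthetic calibration table

The genuinely fitted Weibull parameter table of the source analysis is not
redistributable, so the default configuration uses a **synthetic**
calibrated table (`calibrated_parameter_table()`, every row flagged
`synthetic = TRUE`): a common placeholder shape of 1.3 — a typical
accelerating-hazard value for glioblastoma survival — and scales solved so
each arm's Weibull median equals the published model median
(λ = ln 2 / m^k). Standard errors default to 10% of each estimate with
zero correlation (none are published; the correlation default is exposed).
PFS rows exist only for the cohorts that reported PFS, so the surgery and
age subgroups genuinely exercise the imputation path.

What this emulates: the location of every survival curve (its median), the
full cost/QALY machinery, and the relative ordering of strategies. What it
does not: the true curve *shapes* (and hence restricted means beyond the
median), parameter correlations, and consequently the exact published
totals. Five-year modelled costs land within about 15% of the published
base case in the overall cohort and the orderings agree everywhere, but
QALY levels for the TMZ strategy sit ~0.1 below the published values —
a direct consequence of the placeholder shape. Passing tests therefore
demonstrate correctness of the machinery under a calibrated stand-in, not
decimal reproduction of the published table; dropping a real S1-shaped CSV
into the configuration (`read_parameter_table()`) upgrades the analysis in
place. One published model median (age < 50, RT+TMZ OS) lies outside its
own trial CI in the source table; the validation report reproduces exactly
that single failure.

## Numerical choices and degenerate inputs

- Exhausted survival: the per-cycle exit probability is 1 by convention
  once `S` underflows to 0.
- Median-from-trace uses linear interpolation on the monthly grid
  (≤ 0.05 months from the analytic Weibull median); a curve never crossing
  0.5 raises a median-not-reached error.
- The cloglog fit requires ≥ 3 points with 0 < S < 1, t > 0; hazard fits
  reject non-positive series.
- Beta method-of-moments rejects variances outside the (0,1) support
  rather than silently truncating.
- Seeds: every stochastic entry point (`generate_ipd`, `run_psa`) takes an
  explicit seed; equal seeds give bit-identical output.

## Problem sizes in the shipped tests

The test suite runs the full nine-cohort base case, 20-replicate
parameter-recovery loops at n = 500, PSA determinism/normalization checks
at 40–200 draws, and ellipse coverage at 10⁴ bivariate-normal draws; the
acceptance script uses the full 1,000-draw PSA. These sizes were chosen to
keep the whole suite under a minute while leaving Monte-Carlo standard
errors well inside the asserted tolerances.

## Known limitations

- Partitioned survival cannot separate disease-free→death from
  disease-free→progression flows; the tunnel slightly over-counts
  progression entrants.
- The indirect nitrosourea comparison inherits the shared-shape
  proportional-hazards assumption wholesale.
- Second-line mix and SAE incidences are placeholder configuration values.
- Utilities are borrowed from UK elicitation; no age adjustment.
- The synthetic table reproduces medians, not shapes; see above.
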