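---
title: "Selecting efficient early drought-tolerance traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting efficient early drought-tolerance traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoeff)
```

`phenoeff` implements a pipeline for deciding which traits measured early on
a greenhouse phenotyping platform are worth keeping when the breeding target
is field drought tolerance. This vignette documents the statistical models,
the tunable parameters, the synthetic-data generators used for testing, and
the numerical and design choices a maintainer should know about.

## The pipeline at a glance

1. **Trait extraction** (`platform_traits()`): per-plant daily platform
   records become a long table of atomic observations, one row per
   (trait, day, treatment, genotype, replicate).
2. **Target definition** (`dsi_table()`): the drought susceptibility index
   (DSI) of final shoot dry weight is the quantity the cheap traits must
   predict.
3. **Scoring and selection** (`efficiency_table()`, `select_traits()`):
   every trait × day × treatment combination gets a regression on the
   target, a cost, an efficiency ratio and a repeatability; four criteria
   filter and rank them.
4. **Field validation** (`fit_envelope()`, `classify_environments()`,
   `yield_dsi()`, `delta_y_slope()`, `validate_trait()`): a trial network
   provides independent tolerance estimates the selected trait is regressed
   against.

## Models and formulas

### Growth and water-use traits

Shoot dry weight is estimated from leaf area LA (cm²) and plant age
(days after emergence, DAE) by an affine platform calibration
`SDW = 0.1 + 0.00184·LA + 0.0000926·LA·age` (g). The coefficients are a
property of the platform/species combination and are arguments, not
constants. Relative expansion rate and net assimilation rate use the
classical growth-analysis forms over measurement intervals; NAR's
logarithmic bracket `(ln LA2 − ln LA1)/(LA2 − LA1)` degenerates to `1/LA`
when the areas are equal (its analytic limit), which the implementation
handles explicitly. An alternative NAR variant that *divides* by the bracket
is available behind `formula = "as_printed"`; it is dimensionally a
different quantity and exists only to audit analyses that used that form.
The default is the classical product form.

Daily transpiration comes from the gravimetric balance
`T = (weight_prev + irrigation − weight_today) − evaporation − plant_gain`,
with soil evaporation as the per-day mean of plantless control pots
(carried forward over gaps, flagged) and the plant-weight correction
interpolated linearly between weekly calibration harvests. The weighing
convention is post-irrigation; negative balances (reading noise) clamp to
zero by default while the raw value is kept in an audit column.
Transpiration efficiency is `TE = 1000·SDW / cumulative transpiration from
0 DAE` (g kg⁻¹).

### Drought susceptibility index

For a trait measured under well-watered (ww) and water-deficit (wd)
regimes, `DSI = (1 − y_wd/y_ww)/(1 − x_wd/x_ww)`, where `y` are genotype
means and `x` population means, taken as *unweighted means of genotype
means* so unequal replication does not weight the population. DSI is
scale-invariant and undefined when the population is unaffected. Note that
the mean DSI across genotypes equals 1 exactly only when the well-watered
genotype means share a common value; with unequal baselines the population
reduction is a ratio of means, not a mean of ratios, so mean DSI ≈ 1 but
not identically.

### Variance components and repeatability

Balanced layouts use the closed-form ANOVA expected-mean-squares
estimators (one-way: `σ̂²e = MSE`, `σ̂²g = (MSG − MSE)/r`; two-way random:
`σ̂²ge = (MSGE − MSE)/r`, `σ̂²g = (MSG − MSGE)/(rt)`), which coincide with
REML on balanced data whenever the estimates are interior; the test suite
asserts that equivalence against `lme4::lmer()`. Unbalanced layouts go to
`lmer()` directly. Negative closed-form estimates truncate to zero and are
flagged. Repeatability is `w² = σ²g/(σ²g + σ²e/r)` before the water
treatment starts (all plants share one environment) and
`w² = σ²g/(σ²g + σ²e/(rt) + σ²ge/t)` afterwards, with the soil-water
treatments playing the role of environments. The number of environments `t`
is always an explicit input — whether a given analysis counts the
well-watered control as an environment is a design decision the caller
makes, not a package default.

### The four criteria

For each combination, genotype means are regressed on the per-genotype
target values by ordinary least squares; the two-sided slope p-value comes
from `t = r√((n−2)/(1−r²))`. Phenotyping cost is `replicates × DAE`
(plant·days — platform occupancy is taken as the dominant cost), and the
efficiency ratio is R² divided by the cost relative to the target trait's
cost. The filters are pure predicates (p ≤ α, ratio ≥ 2, optional DAE
ceiling, w² ≥ 0.5), so the surviving set does not depend on evaluation
order; the ranking among survivors is lexicographic (earliest day, then
highest w², then highest ratio). Earliness is implemented as an ordering
preference by default because a hard cutoff is a stronger commitment than
"prefer earlier"; `selection_config(max_dae = )` provides the strict
version. No multiplicity correction is applied across combinations — the
screen is deliberately per-trait, mirroring how such batteries are
triaged in practice — and the full audit table with per-criterion flags is
always returned so a reviewer can re-filter under different thresholds.
Candidate combinations are scored per treatment; DSI-type candidates
(requiring both regimes) are not synthesised automatically, because their
cost accounting (one or two replicate sets?) is genuinely ambiguous — a
caller can compute them with `dsi_table()` and score them explicitly.

### Two-segment VPD response

Transpiration rate (mg m⁻² s⁻¹) against vapour pressure deficit (kPa) is
fitted as two straight lines meeting at a breakpoint BP. Both intercepts
are free parameters — the fit is *not* constrained to be continuous at BP,
matching the four-parameter reporting convention (I₁, S₁, I₂, S₂); a
continuity-constrained variant is available via `continuous = TRUE` for
sensitivity checks. With BP free, the estimate is a grid search (default
resolution 0.01 kPa) minimising total SSE, candidates restricted to leave
at least two distinct-VPD points per side, ties broken toward the smaller
BP. The protocol helper `common_breakpoint()` averages per-genotype free
fits into a single BP that per-plant fits then share. Under realistic noise
(5% of signal, ~30 weighings) the stochastic uncertainty of BP is on the
order of 0.2 kPa — far coarser than the search grid — so per-genotype BP
spreads of a few tenths of a kPa should be read as estimation noise, not
biology.

### Envelope (boundary) analysis of the trial network

Seasonal water input is the pro-rated sum of monthly rainfall from 60 days
before sowing to physiological maturity ("harvest" is taken as
physiological maturity, the only harvest-adjacent date in trial-network
schemas; an explicit harvest date column can be supplied instead when
available). Rainfall is assumed uniform within a month; both window ends
are inclusive. The attainable-yield envelope
`Yield = a(1 − e^{b(w − c)})` is fitted with `b < 0` enforced (the curve
rises and saturates; `a` is attainable yield, `c` the minimum water input
for any yield). "Fit so that 95% of environments lie below the curve" is
realised as asymmetric least squares: squared residuals of points above
the curve are inflated by a weight λ, and λ is raised by bisection until
the on-or-below fraction reaches the smallest achievable value ≥ 0.95.
Environments within ±20% of the envelope prediction (closed band) are
water-limited; among them, critical-period rainfall (< 175 mm vs ≥ 350 mm
between three months and one month before maturity) separates dry, wet and
intermediate environments. Genotype tolerance is then estimated two ways —
yield DSI between dry and wet environments, and the OLS slope of yield
deviations from environment means against water input — and the selected
platform trait is regressed on each.

## Numerical choices

* **Envelope optimiser.** Each λ is fitted by Nelder-Mead on
  (a, log(−b), c), racing a warm start from the previous λ against a cold
  start — warm starts alone can strand the search in a local minimum at
  large λ. The magnitude of b is capped at 0.5 mm⁻¹ to keep the curve away
  from a degenerate step, and non-finite losses are penalised.
* **"Exactly on the curve".** As λ grows, points above the curve are pinned
  onto it from above by an offset shrinking like 1/√λ, never to literal
  zero. A point within 10⁻³ of the yield standard deviation of the curve
  (well under 1 kg ha⁻¹ here) therefore counts as *on* the curve; the
  tolerance is stored on the fit object (`on_curve_tol`) so recounts use
  the same rule. The bisection stops at a relative λ resolution of 10⁻³.
* **Grid search ties** in the segmented fit go to the smallest candidate
  BP; on noise-free data any candidate between the two points flanking the
  true break gives zero SSE, so "recovery" is exact to grid resolution by
  construction.
* **Zero denominators** (ratios at zero shoot mass, TE at zero water, DSI
  with an unaffected population, slope ratios with S₁ = 0) propagate as
  `NA` with a warning or diagnostic, never as errors, so downstream
  regressions drop them explicitly.
* **Convergence of REML** is delegated to `lme4`; the EMS closed forms are
  used wherever the layout is balanced, which is both faster and exactly
  testable.

## The synthetic-data generators

The package is exercised entirely on synthetic data with known truth,
because the analyses it implements are defined by their statistical
structure, not by any particular dataset.

`simulate_platform_experiment()` emulates a seven-genotype screen, two
water regimes (deficit imposed at 33 DAE), eight replicate plants per
genotype per regime, harvest at 57 DAE, and leaf-area measurements at
13/20/27/33/38/44/57 DAE. Leaf area grows exponentially (mean RER
0.12 d⁻¹); the deficit multiplies post-onset RER by a treatment intensity
(0.79) scaled per genotype by a sensitivity multiplier. Daily transpiration
is proportional to transpiring surface (leaf area plus a small seedling
offset) and scaled per plant so that shoot mass per cumulative water equals
the plant's transpiration efficiency at the first measurement day; pot
weights are generated from the same water-balance identity the recovery
uses, so the balance closes exactly, and each recorded weight carries an
independent reading error (1.2 g by default). That noise model reproduces a
key feature of real gravimetric platforms: reading errors dominate
single-day balances of small seedlings but telescope out of cumulative
water use, which is why integrated traits like TE are far more repeatable
early than daily transpiration.

Two structural choices deserve emphasis:

* **The coupling is realised in-sample.** The correlation between genotype
  TE and drought sensitivity (default −0.9) is imposed exactly on the
  simulated panel by orthogonalising the effect vectors, and the
  growth-rate (vigour) effects are constructed exactly orthogonal to both.
  With only seven genotypes, a merely distributional correlation of −0.9
  yields panels whose realised correlation misses the intended structure in
  a sizeable fraction of draws, and unrelated effects pick up large chance
  correlations; a generator whose *conditions* are the stated trait
  architecture must realise that architecture in every run.
* **Noise levels realise the intended trait architecture.** Plant-level
  growth noise (RER sd 0.0015 d⁻¹, ~9% mass CV at harvest), leaf-area
  measurement error (8%), TE plant noise (0.08 g kg⁻¹) and the 1.2 g
  weighing error were chosen, once, as realistic platform values under
  which the built-in TE-sensitivity architecture is actually expressed in
  the extracted tables (TE at 13 DAE strongly correlated with the realised
  DSI, repeatability well above 0.9).

`simulate_field_network()` emulates an 80-environment trial network:
water inputs uniform on 300–1200 mm, environment mean yields on or below a
true envelope (a = 5500 kg ha⁻¹, b = −0.004 mm⁻¹, c = 150 mm) with
constructed shortfalls — 5% of environments marginally above the curve,
12.5% far below it (limited by non-water factors), the rest within the
water-limited band — and per-genotype yields built from sensitivity slopes
coupled (again exactly, −0.9) to a genotype trait value. Monthly rainfall
series are constructed so the pro-rated water-input and critical-period
sums reproduce each environment's targets exactly, which makes the window
arithmetic testable to machine precision.

**What the generators do not emulate**: real platforms have spatial
greenhouse gradients, missing days, sensor drift and genotype-specific
phenology; real trial networks have unbalanced genotype panels across
environments, maturity-group confounding, soil heterogeneity and correlated
weather. Passing tests on this synthetic structure demonstrates that the
*computations* are correct and that the framework recovers a known signal
under realistic noise — not that any particular field outcome will
replicate.

## Problem sizes used by the test suite and acceptance script

Structural tests run a reduced design (5 genotypes × 4 replicates,
25 days). The property checks use the full study conditions: 100 seeded
platform runs for selection recovery, 500 balanced simulations for
repeatability calibration (σ²g = 2, σ²e = 1, r = 8, 10 genotypes),
200 replicates for breakpoint precision (n = 30, 5% noise), 80-environment
networks for envelope recovery and 200 seeded networks for the validation
regressions. These sizes keep the whole suite at a few minutes on one CPU
while leaving Monte-Carlo error well below the asserted margins.

## Known limitations

* The efficiency framework's significance screen at seven genotypes has
  low power and no multiplicity control; with hundreds of candidate
  combinations, occasional false survivors are expected and the audit
  table, not the top line, is the primary output.
* The envelope fit is a heuristic realisation of an ill-posed instruction
  ("fit so that 95% are below"); different asymmetric-loss schedules give
  slightly different (a, b, c) at the same on-or-below fraction.
* Pro-rating monthly rainfall assumes uniform within-month distribution;
  daily weather would sharpen the critical-period classification.
* `leaf_area_from_leaflets()` requires its shape coefficient explicitly:
  the coefficient is cultivar-dependent and defaulting it silently would
  bake a calibration into the package.
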