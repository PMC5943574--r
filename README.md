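# phenoeff

Tools for deciding **which early greenhouse-platform traits are worth
phenotyping** when the goal is predicting field drought tolerance of crop
genotypes (the motivating system is soybean on a gravimetric pot platform).

Breeding programmes can measure dozens of traits on an automated platform —
leaf area, growth rates, water use, canopy temperature — at many time points
and under several watering regimes. Most of these trait-by-time-by-treatment
combinations are expensive and redundant. `phenoeff` implements a complete,
testable pipeline that scores every combination against a drought-tolerance
target and selects the most *efficient* ones, then validates the winner
against multi-environment field-trial data.

## What it computes

**Platform traits** (from per-plant daily records):

* shoot dry weight from leaf area and age, `SDW = c0 + c1·LA + c2·LA·age`;
* classical growth analysis: relative expansion rate
  `RER = (ln LA2 − ln LA1)/(t2 − t1)`, net assimilation rate
  `NAR = (ΔSDW/Δt)·(Δln LA/ΔLA)`, LAR, SLA, and mass-partitioning ratios;
* gravimetric water use: daily transpiration from pot weighings corrected
  for soil evaporation (plantless control pots) and plant fresh-weight gain,
  and transpiration efficiency `TE = 1000·SDW / cumulative water` (g kg⁻¹);
* the two-segment linear response of transpiration rate to vapour pressure
  deficit, `TR = I1 + S1·VPD` below a breakpoint `BP` and `TR = I2 + S2·VPD`
  above it, with a common breakpoint averaged across genotypes.

**Tolerance statistics**:

* drought susceptibility index per genotype,
  `DSI = (1 − Y_wd/Y_ww) / (1 − X_wd/X_ww)`
  (1 = average susceptibility, 0 = unaffected, negative = improves under
  deficit);
* variance components (genotypic, residual, genotype-by-environment) by
  balanced expected-mean-squares estimators or REML, and repeatability
  `w² = σ²g/(σ²g + σ²e/r)` (single environment) or
  `w² = σ²g/(σ²g + σ²e/(rt) + σ²ge/t)` (multi-environment).

**The four-criterion selection framework**: every trait × day × treatment
combination is scored by (1) significance of its regression on the target
DSI (p ≤ 0.05), (2) the ratio of that regression's R² to the relative
phenotyping cost in plant·days (ratio ≥ 2), (3) earliness (days after
emergence), and (4) repeatability (w² ≥ 0.5). Survivors are ranked earliest
first.

**Field-network validation**: seasonal water input from monthly rainfall, a
saturating envelope (boundary) fit
`Yield = a(1 − e^{b(water − c)})` adjusted so ≥95% of environments lie on or
below the curve, classification of environments as water-limited (mean yield
within ±20% of the envelope) and as dry / intermediate / wet by
critical-period rainfall (<175 mm / ≥350 mm), per-genotype yield DSI and
ΔY-vs-water slopes, and the final regression of the selected platform trait
on those field tolerance estimates.

**Synthetic data generators** for both experiment types, with known ground
truth (genotype effects, sensitivity multipliers, envelope parameters), so
every stage is testable end to end without any external data.

## Worked example

```r
library(phenoeff)
res <- run_pipeline(seed = 5, score_dae = c(13, 20, 27, 33, 38, 44, 57))
res$selected[, c("trait", "dae", "treatment", "r2", "p_value", "ratio", "w2")]
#> # A tibble: 1 × 7
#>   trait   dae treatment    r2 p_value ratio    w2
#>   <chr> <int> <chr>     <dbl>   <dbl> <dbl> <dbl>
#> 1 TE       13 WW        0.805 0.00615  3.53 0.955
```

Transpiration efficiency measured at 13 days after emergence under
well-watered conditions is ranked the most efficient trait: its genotype
means explain 80% of the variance in the drought susceptibility index for
final shoot dry weight (p = 0.006), it costs a fraction of the target trait
(efficiency ratio 3.5), it is the earliest surviving trait, and it is highly
repeatable (w² = 0.95).

The target itself, per genotype (`res$target`): DSI for final shoot dry
weight ranges from 0.46 (most tolerant genotype) to 1.28 (most susceptible)
in this run. The field half of the pipeline fits the yield envelope
(`res$envelope`: a = 5515 kg ha⁻¹, b = −0.0038 mm⁻¹, c = 135 mm, 95% of the
80 environments on or below the curve) and validates the selected trait
against both field tolerance measures (`res$validation`):

```
#>   tolerance_measure    r2 p_value   slope
#> 1 dsi_yield         0.544  0.0587 -0.112
#> 2 delta_y_slope     0.585  0.0451 -0.0483
```

Negative slopes mean high-TE genotypes tolerate drought — the platform trait
carries field-relevant signal.

Each stage is also callable on its own (`platform_traits()`, `dsi_table()`,
`efficiency_table()` + `select_traits()`, `fit_two_segment()`,
`fit_envelope()` + `classify_environments()`, `yield_dsi()`,
`delta_y_slope()`, `validate_trait()`), and fitted objects support
`tidy()`, `glance()`, `predict()` and `autoplot()`.

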