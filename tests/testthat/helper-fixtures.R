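# Small in-code fixtures shared across test files.

# Two plants observed on three days, all columns valid.
tiny_plants <- function() {
  tidyr::expand_grid(
    plant_id = c("p1", "p2"), dae = 1:3
  ) |>
    dplyr::mutate(
      genotype = ifelse(plant_id == "p1", "A", "B"),
      treatment = "WW",
      replicate = 1L,
      leaf_area = 10 * dae,
      pot_weight = 5000,
      irrigation_added = 20
    )
}

tiny_platform <- function(plants = tiny_plants()) {
  platform_dataset(
    plants = plants,
    evaporation = tibble::tibble(dae = 1:3, pot_id = "E1", evaporation = 10),
    treatment_onset_dae = 2,
    experiment_id = "fixture"
  )
}

# A small, fast platform simulation for structural tests.
small_platform_config <- function(seed = 1, ...) {
  platform_sim_config(
    n_genotypes = 5, n_replicates = 4, final_dae = 24, onset_dae = 12,
    measurement_dae = c(6, 12, 18, 24),
    gs_dae = c(8, 16), leaf_temp_dae = c(8, 16),
    seed = seed, ...
  )
}

# Independent simple-regression oracle: r2 from squared Pearson correlation,
# p from the textbook t statistic t = r * sqrt((n - 2) / (1 - r2)).
oracle_regression <- function(x, y) {
  n <- length(x)
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r2 = r^2, p = 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE),
       slope = cov(x, y) / var(x))
}

# Independent exhaustive two-segment scan (lm-based), for oracle checks.
oracle_segment_scan <- function(vpd, tr, grid = 0.01) {
  cands <- seq(ceiling(min(vpd) / grid) * grid,
               floor(max(vpd) / grid) * grid, by = grid)
  best <- list(sse = Inf, bp = NA)
  for (bp in cands) {
    l <- vpd < bp
    if (sum(l) < 2 || sum(!l) < 2 ||
        length(unique(vpd[l])) < 2 || length(unique(vpd[!l])) < 2) next
    f1 <- lm(tr[l] ~ vpd[l])
    f2 <- lm(tr[!l] ~ vpd[!l])
    sse <- sum(resid(f1)^2) + sum(resid(f2)^2)
    if (sse < best$sse) best <- list(sse = sse, bp = bp)
  }
  best
}
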