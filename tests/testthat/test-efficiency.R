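test_that("trait-vs-target regression matches the closed-form textbook oracle", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(7)
    y <- 0.6 * x + rnorm(7, 0, 0.5)
    fit <- trait_vs_target_regression(
      tibble::tibble(genotype = letters[1:7], value = y),
      tibble::tibble(genotype = letters[1:7], target = x)
    )
    oracle <- oracle_regression(x, y)
    expect_equal(fit$r2, oracle$r2, tolerance = 1e-10)
    expect_equal(fit$p_value, oracle$p, tolerance = 1e-10)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    # and against lm/summary.lm as a second, independent route
    lmfit <- summary(lm(y ~ x))
    expect_equal(fit$r2, lmfit$r.squared, tolerance = 1e-10)
    expect_equal(fit$p_value, lmfit$coefficients[2, 4], tolerance = 1e-10)
  }
})

test_that("a perfectly linear trait gives r2 = 1 and a vanishing p", {
  x <- 1:7
  fit <- trait_vs_target_regression(
    tibble::tibble(genotype = letters[1:7], value = 3 - 2 * x),
    tibble::tibble(genotype = letters[1:7], target = x)
  )
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-12)
  expect_equal(fit$slope, -2, tolerance = 1e-12)
})

test_that("permuted labels give uniform p-values (null calibration)", {
  set.seed(77)
  x <- rnorm(7)
  ps <- vapply(1:1000, function(i) {
    # fresh replicate-level trait values, genotype labels then permuted so
    # any association with the target is destroyed by construction
    trait_vs_target_regression(
      tibble::tibble(genotype = letters[1:7], value = sample(rnorm(7))),
      tibble::tibble(genotype = letters[1:7], target = x)
    )$p_value
  }, numeric(1))
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("phenotyping cost is replicates times occupancy days", {
  expect_equal(phenotyping_cost(10, 13), 130)
  expect_equal(phenotyping_cost(1, 1), 1)
  expect_equal(phenotyping_cost(2:6, 13), (2:6) * 13)
  expect_error(phenotyping_cost(0, 13), class = "phenoeff_domain_error")
})

test_that("efficiency ratio scales r2 by the relative cost", {
  expect_equal(efficiency_ratio(0.7, 130, 570), 0.7 / (130 / 570),
               tolerance = 1e-12)
  expect_equal(efficiency_ratio(0.7, 130, 570), 3.069, tolerance = 1e-3)
  expect_equal(efficiency_ratio(1, 570, 570), 1)
  expect_equal(efficiency_ratio(0.5, 100, 400),
               2 * efficiency_ratio(0.5, 200, 400))
  expect_error(efficiency_ratio(0.5, 0, 100), class = "phenoeff_domain_error")
})

# A 20-row audit fixture with known pass/fail structure.
audit_fixture <- function() {
  set.seed(55)
  tibble::tibble(
    trait = paste0("t", 1:20),
    dae = rep(c(13, 20, 33, 44, 57), 4),
    treatment = rep(c("WW", "WD"), 10),
    n_genotypes = 7,
    n_replicates = 8,
    r2 = runif(20, 0, 1),
    p_value = runif(20, 0, 0.2),
    slope = rnorm(20),
    cost = rep(c(13, 20, 33, 44, 57), 4) * 8,
    relative_cost = rep(c(13, 20, 33, 44, 57), 4) / 57,
    w2 = runif(20, 0.2, 1)
  ) |>
    dplyr::mutate(ratio = r2 / relative_cost)
}

test_that("selection filters match an independent filter-by-filter recount", {
  rows <- audit_fixture()
  cfg <- selection_config(alpha = 0.05, ratio_min = 2, w2_min = 0.5)
  out <- select_traits(rows, cfg)
  # audit table retains every combination exactly once
  expect_equal(nrow(out), nrow(rows))
  expect_setequal(out$trait, rows$trait)
  # brute-force recount per filter
  expect_equal(sum(out$pass_significance), sum(rows$p_value <= 0.05))
  expect_equal(sum(out$pass_ratio), sum(rows$ratio >= 2))
  expect_equal(sum(out$pass_w2), sum(rows$w2 >= 0.5))
  expect_equal(sum(out$selected),
               sum(rows$p_value <= 0.05 & rows$ratio >= 2 & rows$w2 >= 0.5))
  # filters are pure predicates: survivor set is order-independent
  manual <- rows[rows$w2 >= 0.5 & rows$ratio >= 2 & rows$p_value <= 0.05, ]
  expect_setequal(out$trait[out$selected], manual$trait)
})

test_that("a uniquely qualified trait is ranked first; earliness breaks ties", {
  rows <- audit_fixture() |>
    dplyr::mutate(p_value = 0.5, w2 = 0.3) # disqualify everything
  rows$p_value[7] <- 0.01
  rows$w2[7] <- 0.9
  rows$ratio[7] <- 5
  out <- select_traits(rows)
  expect_equal(sum(out$selected), 1)
  expect_equal(out$trait[out$rank == 1 & !is.na(out$rank)], rows$trait[7])

  # two identical traits except measurement day: the earlier one ranks first
  pair <- tibble::tibble(
    trait = c("late", "early"), dae = c(44, 13), treatment = "WW",
    n_genotypes = 7, n_replicates = 8, r2 = 0.8, p_value = 0.01,
    slope = -1, cost = c(44, 13) * 8, relative_cost = c(44, 13) / 57,
    w2 = 0.8
  ) |>
    dplyr::mutate(ratio = r2 / relative_cost)
  ranked <- select_traits(pair)
  expect_equal(ranked$trait[ranked$rank == 1 & !is.na(ranked$rank)], "early")
})

test_that("a hard earliness ceiling excludes late traits when configured", {
  rows <- audit_fixture() |>
    dplyr::mutate(p_value = 0.01, w2 = 0.9, ratio = 5)
  out <- select_traits(rows, selection_config(max_dae = 33))
  expect_true(all(out$dae[out$selected] <= 33))
  expect_true(any(rows$dae > 33)) # the ceiling actually bites
})

test_that("the audit table covers every combination in the observations", {
  sim <- simulate_platform_experiment(small_platform_config(seed = 23))
  obs <- platform_traits(sim$data)
  tgt <- dsi_table(obs, "Shoot dry weight", max(obs$dae))
  eff <- efficiency_table(
    obs, dplyr::transmute(tgt, genotype, target = dsi),
    onset_dae = sim$data$treatment_onset_dae
  )
  combos <- dplyr::distinct(obs, trait, dae, treatment)
  expect_equal(nrow(eff), nrow(combos))
  expect_equal(nrow(dplyr::distinct(eff, trait, dae, treatment)), nrow(eff))
  # ratio column is exactly r2 / relative_cost
  ok <- !is.na(eff$ratio)
  expect_equal(eff$ratio[ok], eff$r2[ok] / eff$relative_cost[ok],
               tolerance = 1e-12)
})
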