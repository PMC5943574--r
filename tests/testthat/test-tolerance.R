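test_that("DSI formula reproduces hand-computed values and edge cases", {
  # genotype reduction equal to the population reduction
  expect_equal(dsi(10, 8, 10, 8), 1)
  expect_equal(dsi(10, 6, 10, 8), 2, tolerance = 1e-12)
  # unaffected genotype
  expect_equal(dsi(10, 10, 10, 8), 0)
  # trait increasing under deficit: negative DSI
  expect_lt(dsi(10, 12, 10, 8), 0)
  # population unaffected: undefined
  expect_warning(out <- dsi(10, 6, 10, 10))
  expect_true(is.na(out))
  expect_error(dsi(0, 5, 10, 8), class = "phenoeff_domain_error")
})

test_that("DSI is invariant to rescaling all trait values", {
  set.seed(2)
  y_ww <- runif(6, 5, 20)
  y_wd <- y_ww * runif(6, 0.4, 0.9)
  x_ww <- mean(y_ww)
  x_wd <- mean(y_wd)
  for (k in c(0.01, 3, 1000)) {
    expect_equal(dsi(k * y_ww, k * y_wd, k * x_ww, k * x_wd),
                 dsi(y_ww, y_wd, x_ww, x_wd), tolerance = 1e-12)
  }
})

test_that("dsi_table computes genotype and population means correctly", {
  mk_obs <- function(ratios) {
    genos <- sprintf("g%d", seq_along(ratios))
    dplyr::bind_rows(
      tibble::tibble(trait = "x", dae = 5L, treatment = "WW", genotype = genos,
                     replicate = 1L, value = 10),
      tibble::tibble(trait = "x", dae = 5L, treatment = "WD", genotype = genos,
                     replicate = 1L, value = 10 * ratios)
    )
  }
  # homogeneous population: every DSI is 1
  hom <- dsi_table(mk_obs(rep(0.7, 4)), "x", 5)
  expect_equal(hom$dsi, rep(1, 4), tolerance = 1e-12)
  # ratios 0.5 / 0.7 / 0.9 around population ratio 0.7
  tbl <- dsi_table(mk_obs(c(0.5, 0.7, 0.9)), "x", 5)
  expect_equal(tbl$dsi, c(5 / 3, 1, 1 / 3), tolerance = 1e-12)
})

test_that("dsi_table matches a spreadsheet-style recomputation on simulated data", {
  sim <- simulate_platform_experiment(small_platform_config(seed = 17))
  obs <- platform_traits(sim$data)
  final <- max(obs$dae)
  tbl <- dsi_table(obs, "Shoot dry weight", final)

  # independent recomputation with base aggregation
  sel <- obs[obs$trait == "Shoot dry weight" & obs$dae == final, ]
  gm <- tapply(sel$value, list(sel$genotype, sel$treatment), mean)
  x_ww <- mean(gm[, "WW"])
  x_wd <- mean(gm[, "WD"])
  manual <- (1 - gm[, "WD"] / gm[, "WW"]) / (1 - x_wd / x_ww)
  expect_equal(tbl$dsi, unname(manual[tbl$genotype]), tolerance = 1e-12)
})

test_that("genotypes missing a regime are excluded from table and population means", {
  obs <- dplyr::bind_rows(
    tibble::tibble(trait = "x", dae = 1L, treatment = "WW",
                   genotype = c("a", "b", "c"), replicate = 1L,
                   value = c(10, 10, 10)),
    tibble::tibble(trait = "x", dae = 1L, treatment = "WD",
                   genotype = c("a", "b"), replicate = 1L, value = c(5, 9))
  )
  tbl <- dsi_table(obs, "x", 1)
  expect_equal(sort(tbl$genotype), c("a", "b"))
  expect_equal(attr(tbl, "excluded"), "c")
  expect_equal(tbl$x_wd[1], 7) # mean of a and b only
})

test_that("mean genotype reduction normalizes to the population reduction", {
  # with a common well-watered baseline the unweighted mean of genotype
  # reductions equals the population reduction, so the DSI averages to 1;
  # with unequal baselines the two differ (ratio of means vs mean of ratios)
  set.seed(6)
  ratios <- runif(8, 0.3, 0.95)
  mk <- function(base) {
    dplyr::bind_rows(
      tibble::tibble(trait = "x", dae = 1L, treatment = "WW",
                     genotype = sprintf("g%d", 1:8), replicate = 1L,
                     value = base),
      tibble::tibble(trait = "x", dae = 1L, treatment = "WD",
                     genotype = sprintf("g%d", 1:8), replicate = 1L,
                     value = base * ratios)
    )
  }
  tbl <- dsi_table(mk(rep(10, 8)), "x", 1)
  expect_equal(mean(1 - tbl$y_wd / tbl$y_ww), 1 - tbl$x_wd[1] / tbl$x_ww[1],
               tolerance = 1e-12)
  expect_equal(mean(tbl$dsi), 1, tolerance = 1e-12)
})

test_that("variance components: degenerate, EMS formulas, REML equivalence", {
  flat <- tibble::tibble(genotype = rep(c("a", "b"), each = 3), value = 4)
  vc0 <- variance_components(flat, "one_way")
  expect_equal(vc0$sigma2_g, 0)
  expect_equal(vc0$sigma2_e, 0)

  set.seed(31)
  one <- tibble::tibble(
    genotype = rep(sprintf("g%d", 1:6), each = 5),
    value = rep(rnorm(6, 10, 1.5), each = 5) + rnorm(30, 0, 0.7)
  )
  vc <- variance_components(one, "one_way")
  # closed-form check against aov mean squares
  ms <- summary(stats::aov(value ~ genotype, data = one))[[1]]$`Mean Sq`
  expect_equal(vc$sigma2_e, ms[2], tolerance = 1e-10)
  expect_equal(vc$sigma2_g, (ms[1] - ms[2]) / 5, tolerance = 1e-10)
  # balanced EMS equals lme4 REML when estimates are nonnegative
  fit <- lme4::lmer(value ~ (1 | genotype), data = one, REML = TRUE)
  reml <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(vc$sigma2_g, reml$vcov[reml$grp == "genotype"], tolerance = 1e-6)
  expect_equal(vc$sigma2_e, reml$vcov[reml$grp == "Residual"], tolerance = 1e-6)
})

test_that("two-way EMS estimates equal REML on balanced data when nonnegative", {
  set.seed(8)
  obs <- tidyr::expand_grid(genotype = sprintf("g%d", 1:6),
                            environment = c("WW", "WD1", "WD2"), rep = 1:4)
  obs$value <- rep(rnorm(6, 20, 2), each = 12) +
    rep(rnorm(18, 0, 0.9), each = 4) + rnorm(72, 0, 0.6)
  vc <- variance_components(obs, "two_way")
  expect_equal(vc$method, "ems")
  fit <- lme4::lmer(
    value ~ environment + (1 | genotype) + (1 | genotype:environment),
    data = obs, REML = TRUE
  )
  reml <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(vc$sigma2_g, reml$vcov[reml$grp == "genotype"], tolerance = 1e-4)
  expect_equal(vc$sigma2_ge, reml$vcov[reml$grp == "genotype:environment"],
               tolerance = 1e-4)
  expect_equal(vc$sigma2_e, reml$vcov[reml$grp == "Residual"], tolerance = 1e-4)
})

test_that("unbalanced layouts fall back to REML and negatives truncate", {
  set.seed(9)
  unb <- tibble::tibble(
    genotype = rep(sprintf("g%d", 1:5), times = c(3, 4, 5, 3, 6)),
    value = rnorm(21, 10, 1)
  )
  vc <- variance_components(unb, "one_way")
  expect_equal(vc$method, "reml")
  expect_gte(vc$sigma2_g, 0)
  # pure-noise balanced data frequently truncates the genotypic component
  noise <- tibble::tibble(genotype = rep(c("a", "b", "c"), each = 10),
                          value = c(scale(rnorm(30))))
  vcn <- variance_components(noise, "one_way")
  expect_gte(vcn$sigma2_g, 0)
  expect_error(variance_components(tibble::tibble(genotype = "a", value = 1),
                                   "one_way"),
               class = "phenoeff_estimation_error")
})

test_that("repeatability follows the single- and multi-environment forms", {
  one <- tibble::tibble(sigma2_g = 1, sigma2_e = 1, sigma2_ge = NA, r = 4, t = 1)
  expect_equal(repeatability(one, "single_env"), 0.8, tolerance = 1e-12)
  expect_equal(repeatability(dplyr::mutate(one, sigma2_g = 0), "single_env"), 0)
  expect_equal(repeatability(dplyr::mutate(one, sigma2_e = 0), "single_env"), 1)
  multi <- tibble::tibble(sigma2_g = 2, sigma2_e = 1, sigma2_ge = 0.5,
                          r = 4, t = 2)
  expect_equal(repeatability(multi, "multi_env"),
               2 / (2 + 1 / 8 + 0.5 / 2), tolerance = 1e-12)
  expect_warning(
    nad <- repeatability(tibble::tibble(sigma2_g = 0, sigma2_e = 0, r = 3),
                         "single_env")
  )
  expect_true(is.na(nad))
})

test_that("repeatability increases with replication and environments", {
  base <- tibble::tibble(sigma2_g = 1.5, sigma2_e = 2, sigma2_ge = 0.8,
                         r = 2, t = 2)
  w_r <- vapply(2:10, function(r) repeatability(base, "multi_env", r = r),
                numeric(1))
  expect_true(all(diff(w_r) > 0))
  w_t <- vapply(2:8, function(t) repeatability(base, "multi_env", t = t),
                numeric(1))
  expect_true(all(diff(w_t) > 0))
})
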