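# A single-environment field dataset with configurable dates and rainfall.
mk_env <- function(rain_by_month, sowing, maturity, env = "E1") {
  trials <- tibble::tibble(
    environment_id = env, genotype = c("g1", "g2"), yield = 3000,
    sowing_date = as.Date(sowing), emergence_date = as.Date(sowing) + 8,
    maturity_date = as.Date(maturity)
  )
  rainfall <- tibble::tibble(
    environment_id = env,
    month = as.Date(names(rain_by_month)),
    rainfall_mm = unname(rain_by_month)
  )
  field_dataset(trials, rainfall)
}

test_that("water input sums rainfall over [sowing - 60 d, maturity] pro rata", {
  # window 2014-09-02 .. 2015-01-31 with uniform 100 mm/month
  months <- seq(as.Date("2014-08-01"), as.Date("2015-02-01"), by = "month")
  fd <- mk_env(setNames(rep(100, 7), as.character(months)),
               "2014-11-01", "2015-01-31")
  wi <- water_input(fd)
  # Sep is covered from the 2nd: 29/30 of September counts
  expect_equal(wi$water_input, 100 * (29 / 30 + 4), tolerance = 1e-9)

  # mid-month start: 15 of 30 September days -> half the month's 60 mm
  fd2 <- mk_env(c("2014-09-01" = 60, "2014-10-01" = 0, "2014-11-01" = 0,
                  "2014-12-01" = 0),
                "2014-11-15", "2014-12-31")
  expect_equal(water_input(fd2)$water_input, 30, tolerance = 1e-9)

  # zero rainfall everywhere
  fd3 <- mk_env(c("2014-09-01" = 0, "2014-10-01" = 0, "2014-11-01" = 0,
                  "2014-12-01" = 0),
                "2014-11-01", "2014-12-15")
  expect_equal(water_input(fd3)$water_input, 0)
})

test_that("critical-period rainfall covers [maturity - 3 m, maturity - 1 m]", {
  months <- seq(as.Date("2014-09-01"), as.Date("2015-04-01"), by = "month")
  fd <- mk_env(setNames(rep(100, 8), as.character(months)),
               "2014-11-01", "2015-03-31")
  # window 2014-12-31 .. 2015-02-28: 1/31 Dec + Jan + Feb
  expect_equal(critical_period_rainfall(fd)$critical_rainfall,
               100 * (1 / 31 + 1 + 1), tolerance = 1e-9)

  # all rain outside the window contributes nothing
  fd2 <- mk_env(c("2014-09-01" = 500, "2014-10-01" = 0, "2014-11-01" = 0,
                  "2014-12-01" = 0, "2015-01-01" = 0, "2015-02-01" = 0,
                  "2015-03-01" = 0),
                "2014-11-01", "2015-03-31")
  expect_equal(critical_period_rainfall(fd2)$critical_rainfall, 0)
})

test_that("window sums equal a brute-force daily accumulation oracle", {
  set.seed(19)
  months <- seq(as.Date("2014-08-01"), as.Date("2015-05-01"), by = "month")
  rain <- setNames(round(runif(10, 0, 200)), as.character(months))
  fd <- mk_env(rain, "2014-11-13", "2015-04-07")
  # daily expansion: rain_m / days_in_month on every day of month m
  daily <- do.call(rbind, lapply(seq_along(months), function(i) {
    days <- seq(months[i], lubridate::ceiling_date(months[i], "month") - 1, 1)
    data.frame(day = days, mm = unname(rain[i]) / length(days))
  }))
  w_start <- as.Date("2014-11-13") - 60
  w_end <- as.Date("2015-04-07")
  expect_equal(water_input(fd)$water_input,
               sum(daily$mm[daily$day >= w_start & daily$day <= w_end]),
               tolerance = 1e-9)
  c_start <- lubridate::add_with_rollback(w_end, -months(3))
  c_end <- lubridate::add_with_rollback(w_end, -months(1))
  expect_equal(critical_period_rainfall(fd)$critical_rainfall,
               sum(daily$mm[daily$day >= c_start & daily$day <= c_end]),
               tolerance = 1e-9)
})

test_that("envelope fit recovers known parameters with constructed shortfalls", {
  fsim <- simulate_field_network(field_sim_config(seed = 4))
  fd <- fsim$data
  wi <- water_input(fd)
  em <- fd$trials |>
    dplyr::group_by(environment_id) |>
    dplyr::summarise(mean_yield = mean(yield)) |>
    dplyr::inner_join(wi, by = "environment_id")
  fit <- fit_envelope(em)
  expect_lt(abs(fit$a - 5500) / 5500, 0.10)
  expect_gte(fit$fraction_below, 0.95)
  # independent recount of the on-or-below fraction
  pred <- predict(fit, em)
  expect_equal(fit$fraction_below, mean(em$mean_yield <= pred + fit$on_curve_tol))
  # the curve predicts zero yield at the minimum water input c
  expect_equal(predict(fit, tibble::tibble(water_input = fit$c)), 0,
               tolerance = 1e-9)
  # bisection trace: the on-or-below fraction rises (weakly) with the weight
  tr <- dplyr::arrange(fit$trace, lambda)
  expect_true(all(diff(tr$fraction_below) >= -1e-9))
})

test_that("noise-free environments on the curve are recovered exactly", {
  set.seed(5)
  w <- seq(200, 1200, length.out = 30)
  em <- tibble::tibble(water_input = w,
                       mean_yield = 5500 * (1 - exp(-0.004 * (w - 150))))
  fit <- fit_envelope(em)
  expect_equal(fit$fraction_below, 1)
  expect_lt(abs(fit$a - 5500) / 5500, 0.02)
  expect_lt(abs(fit$c - 150), 25)
})

test_that("environment classification applies the closed band and rain cutoffs", {
  fsim <- simulate_field_network(field_sim_config(seed = 6, n_environments = 20))
  fd <- fsim$data
  wi <- water_input(fd)
  crit <- critical_period_rainfall(fd)
  em <- fd$trials |>
    dplyr::group_by(environment_id) |>
    dplyr::summarise(mean_yield = mean(yield)) |>
    dplyr::inner_join(wi, by = "environment_id") |>
    dplyr::inner_join(crit, by = "environment_id")
  fit <- fit_envelope(em)
  cl <- classify_environments(em, fit, band = 0.20, dry_mm = 175)
  # brute-force reclassification
  pred <- predict(fit, em)
  wl <- em$mean_yield >= 0.8 * pred & em$mean_yield <= 1.2 * pred
  manual <- ifelse(!wl, "excluded",
                   ifelse(em$critical_rainfall < 175, "dry",
                          ifelse(em$critical_rainfall >= 350, "wet",
                                 "intermediate")))
  expect_equal(as.character(cl$moisture_class), manual)
  # partition-complete: exactly one class per environment
  expect_false(anyNA(cl$moisture_class))
  expect_equal(nrow(cl), 20)
  # idempotent
  cl2 <- classify_environments(cl, fit, band = 0.20, dry_mm = 175)
  expect_equal(as.character(cl2$moisture_class), as.character(cl$moisture_class))
})

test_that("band edges: on-curve is water-limited, below 0.80 is excluded", {
  fit <- structure(list(a = 5000, b = -0.004, c = 150, fraction_below = 1,
                        lambda = 1, n = 10, trace = tibble::tibble(),
                        data = tibble::tibble(water_input = 500,
                                              mean_yield = 4000)),
                   class = "envelope_fit")
  pred <- predict(fit, tibble::tibble(water_input = 600))
  envs <- tibble::tibble(
    environment_id = c("mid", "low", "edge"), water_input = 600,
    mean_yield = c(pred, 0.79 * pred, 0.80 * pred),
    critical_rainfall = 100
  )
  cl <- classify_environments(envs, fit)
  expect_equal(cl$water_limited, c(TRUE, FALSE, TRUE))
  expect_equal(as.character(cl$moisture_class), c("dry", "excluded", "dry"))
})

test_that("yield DSI across dry and wet environments matches hand values", {
  classes <- tibble::tibble(
    environment_id = c("D1", "D2", "W1", "W2"),
    moisture_class = factor(c("dry", "dry", "wet", "wet"),
                            levels = c("dry", "intermediate", "wet", "excluded"))
  )
  trials <- tidyr::expand_grid(environment_id = classes$environment_id,
                               genotype = c("g1", "g2")) |>
    dplyr::mutate(yield = dplyr::case_when(
      genotype == "g1" & environment_id %in% c("D1", "D2") ~ 3000, # ratio 0.6
      genotype == "g1" ~ 5000,
      genotype == "g2" & environment_id %in% c("D1", "D2") ~ 4000, # ratio 0.8
      TRUE ~ 5000
    ))
  td <- yield_dsi(trials, classes)
  expect_equal(td$dsi_yield[td$genotype == "g1"], 4 / 3, tolerance = 1e-12)
  expect_equal(td$dsi_yield[td$genotype == "g2"], 2 / 3, tolerance = 1e-12)
  # population-average behaviour gives DSI 1
  same <- dplyr::mutate(trials, yield = ifelse(environment_id %in% c("D1", "D2"),
                                               3500, 5000))
  expect_equal(yield_dsi(same, classes)$dsi_yield, c(1, 1), tolerance = 1e-12)
  # a genotype yielding more in dry than wet environments goes negative,
  # provided the population as a whole is still reduced under drought
  inv <- trials
  inv$yield[inv$genotype == "g1" & inv$environment_id %in% c("D1", "D2")] <- 5500
  expect_lt(yield_dsi(inv, classes)$dsi_yield[1], 0)
})

test_that("delta-Y slope recovers constructed sensitivity and the closed form", {
  water <- tibble::tibble(environment_id = sprintf("E%d", 1:6),
                          water_input = c(300, 450, 600, 750, 900, 1050))
  base <- tidyr::expand_grid(environment_id = water$environment_id,
                             genotype = c("g1", "g2")) |>
    dplyr::inner_join(water, by = "environment_id")
  # g1 deviates as +0.5 * (water - mean water); g2 mirrors it
  base$yield <- 4000 + ifelse(base$genotype == "g1", 0.5, -0.5) *
    (base$water_input - mean(water$water_input))
  sl <- delta_y_slope(base, water)
  expect_equal(sl$delta_y_slope[sl$genotype == "g1"], 0.5, tolerance = 1e-10)
  expect_equal(sl$delta_y_slope[sl$genotype == "g2"], -0.5, tolerance = 1e-10)

  # genotype always at the environment mean: slope 0
  flat <- dplyr::mutate(base, yield = 4000)
  expect_equal(delta_y_slope(flat, water)$delta_y_slope, c(0, 0))

  # closed form cov/var oracle on noisy data
  set.seed(14)
  noisy <- dplyr::mutate(base, yield = yield + rnorm(12, 0, 50))
  sl2 <- delta_y_slope(noisy, water)
  dy <- noisy |>
    dplyr::group_by(environment_id) |>
    dplyr::mutate(dy = yield - mean(yield)) |>
    dplyr::ungroup()
  g1 <- dy[dy$genotype == "g1", ]
  expect_equal(sl2$delta_y_slope[sl2$genotype == "g1"],
               cov(g1$dy, g1$water_input) / var(g1$water_input),
               tolerance = 1e-10)
})

test_that("trait validation regression reports R2, p and slope sign", {
  tol <- tibble::tibble(genotype = letters[1:7], dsi_yield = seq(0.4, 1.6, 0.2))
  anti <- tibble::tibble(genotype = letters[1:7],
                         value = 5 - 2 * tol$dsi_yield)
  v <- validate_trait(anti, tol)
  expect_equal(v$r2, 1, tolerance = 1e-12)
  expect_lt(v$slope, 0)
  set.seed(3)
  noisy <- tibble::tibble(genotype = letters[1:7],
                          value = 5 - 2 * tol$dsi_yield + rnorm(7, 0, 0.3))
  v2 <- validate_trait(noisy, tol)
  expect_equal(v2$r2, cor(noisy$value, tol$dsi_yield)^2, tolerance = 1e-12)
})
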