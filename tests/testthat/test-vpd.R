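test_that("noise-free generative recovery returns the true segment parameters", {
  d <- simulate_vpd_series(i1 = 0, s1 = 20, i2 = 30, s2 = 8, bp = 2.5,
                           n = 40, vpd_range = c(1.2, 3.0), noise_sd = 0,
                           seed = 21)
  fit <- fit_two_segment(d, bp_grid = 0.01)
  expect_equal(fit$i1, 0, tolerance = 1e-8)
  expect_equal(fit$s1, 20, tolerance = 1e-8)
  expect_equal(fit$i2, 30, tolerance = 1e-6)
  expect_equal(fit$s2, 8, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-16)
  # recovered breakpoint within one grid step of the truth
  expect_lt(abs(fit$bp - 2.5), 0.01 + 1e-12)
})

test_that("a single straight line degenerates to equal segments with ratio 1", {
  d <- simulate_vpd_series(i1 = 5, s1 = 12, i2 = 5, s2 = 12, bp = 2,
                           n = 30, noise_sd = 0, seed = 3)
  fit <- fit_two_segment(d, bp_grid = 0.05)
  expect_equal(fit$s1, fit$s2, tolerance = 1e-6)
  expect_equal(fit$i1, fit$i2, tolerance = 1e-5)
  expect_equal(derived_params(fit)$s2_s1_ratio, 1, tolerance = 1e-6)
})

test_that("grid-search breakpoint equals the exhaustive lm-based oracle", {
  for (seed in c(7, 8, 9)) {
    d <- simulate_vpd_series(n = 30, noise_sd = 0.05, seed = seed)
    fit <- fit_two_segment(d, bp_grid = 0.01)
    oracle <- oracle_segment_scan(d$vpd, d$tr, grid = 0.01)
    expect_equal(fit$bp, oracle$bp)
    expect_equal(fit$sse, oracle$sse, tolerance = 1e-8)
  }
})

test_that("fixed-breakpoint OLS matches the grid candidate at that breakpoint", {
  d <- simulate_vpd_series(n = 30, noise_sd = 0.05, seed = 12)
  free <- fit_two_segment(d, bp_grid = 0.01)
  fixed <- fit_two_segment(d, bp_fixed = free$bp)
  expect_equal(fixed$sse, free$sse, tolerance = 1e-10)
  # fixing at the truth cannot beat the grid optimum at its own resolution
  at_truth <- fit_two_segment(d, bp_fixed = 2.5)
  expect_gte(at_truth$sse, free$sse - 1e-10)
})

test_that("stochastic breakpoint precision stays within the noise floor", {
  # 5%-of-signal noise at n = 30: the breakpoint's stochastic uncertainty is
  # a couple of tenths of a kPa; a broken fitter inflates this drastically
  errs <- vapply(1:60, function(i) {
    d <- simulate_vpd_series(n = 30, noise_sd = 0.05, seed = 100 + i)
    abs(fit_two_segment(d, bp_grid = 0.02)$bp - 2.5)
  }, numeric(1))
  expect_lt(median(errs), 0.25)
})

test_that("per-plant fits with a common fixed BP average to the pooled fit when balanced", {
  # noise-free plants of one genotype share the same true response
  plants <- lapply(1:4, function(i) {
    simulate_vpd_series(i1 = 2, s1 = 18, i2 = 25, s2 = 7, bp = 2.4,
                        n = 24, noise_sd = 0, seed = 30 + i)
  })
  fits <- lapply(plants, fit_two_segment, bp_fixed = 2.4)
  pooled <- fit_two_segment(dplyr::bind_rows(plants), bp_fixed = 2.4)
  expect_equal(mean(vapply(fits, function(f) f$s1, numeric(1))), pooled$s1,
               tolerance = 1e-8)
  expect_equal(mean(vapply(fits, function(f) f$i2, numeric(1))), pooled$i2,
               tolerance = 1e-6)
})

test_that("common breakpoint summarises per-genotype fits", {
  cb <- common_breakpoint(c(2.3, 2.5, 2.7))
  expect_equal(cb$mean_bp, 2.5)
  expect_equal(cb$sd_bp, 0.2)
  one <- common_breakpoint(2.4)
  expect_equal(one$mean_bp, 2.4)
  expect_equal(one$sd_bp, 0)
  expect_equal(one$n, 1)
  expect_equal(common_breakpoint(c(2.5, 2.5, 2.5))$sd_bp, 0)
})

test_that("derived parameters follow from the fitted segments", {
  d <- simulate_vpd_series(i1 = 0, s1 = 20, i2 = 30, s2 = 8, bp = 2.5,
                           n = 40, noise_sd = 0, seed = 40)
  fit <- fit_two_segment(d, bp_fixed = 2.5)
  dp <- derived_params(fit, vpd_max = 2.98)
  expect_equal(dp$tr_bp, 0 + 20 * 2.5, tolerance = 1e-6)
  expect_equal(dp$tr_maxvpd, 30 + 8 * 2.98, tolerance = 1e-6)
  expect_equal(dp$s2_s1_ratio, 0.4, tolerance = 1e-8)
  # continuity case: at vpd_max = bp with continuous segments the two match
  dc <- simulate_vpd_series(i1 = 0, s1 = 20, i2 = 30, s2 = 8, bp = 2.5,
                            n = 40, noise_sd = 0, seed = 41)
  fitc <- fit_two_segment(dc, bp_fixed = 2.5)
  dpc <- derived_params(fitc, vpd_max = 2.5)
  expect_equal(dpc$tr_maxvpd, dpc$tr_bp, tolerance = 1e-6)
})

test_that("fit errors name degenerate inputs", {
  few <- tibble::tibble(vpd = c(1, 2, 3), tr = c(1, 2, 3))
  expect_error(fit_two_segment(few), class = "phenoeff_fit_error")
  collinear <- tibble::tibble(vpd = c(1, 1, 3, 4), tr = c(1, 2, 3, 4))
  expect_error(fit_two_segment(collinear, bp_fixed = 2),
               class = "phenoeff_fit_error")
})

test_that("tidiers and plot methods expose the fit", {
  d <- simulate_vpd_series(n = 30, noise_sd = 0.05, seed = 50)
  fit <- fit_two_segment(d)
  td <- tidy(fit)
  expect_equal(td$term, c("i1", "s1", "i2", "s2", "bp"))
  gl <- glance(fit)
  expect_true(gl$r.squared > 0.8)
  expect_s3_class(autoplot(fit), "ggplot")
})
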