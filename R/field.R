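# Pro-rated sum of a monthly rainfall series over an arbitrary date window.
# Rain is assumed uniformly distributed within each month; both window ends
# are inclusive.
.window_rainfall <- function(rainfall, start, end, label = "window") {
  stopifnot(inherits(start, "Date"), inherits(end, "Date"), start <= end)
  windows <- tibble::tibble(environment_id = "x", start = start, end = end)
  rain <- dplyr::mutate(rainfall, environment_id = "x")
  .window_sums(rain, windows, label)$rain_sum
}

# Vectorised pro-rated window sums: one row per environment in `windows`
# (columns environment_id, start, end), joined against the monthly series.
# Coverage is complete iff the summed overlap days equal the window length.
.window_sums <- function(rainfall, windows, label = "window") {
  joined <- dplyr::inner_join(
    rainfall[, c("environment_id", "month", "rainfall_mm")],
    windows, by = "environment_id"
  )
  m_start <- lubridate::floor_date(joined$month, "month")
  m_end <- lubridate::ceiling_date(joined$month, "month") - 1
  m_days <- as.numeric(m_end - m_start) + 1
  o_days <- pmax(
    as.numeric(pmin(m_end, joined$end) - pmax(m_start, joined$start)) + 1, 0
  )
  out <- tibble::tibble(
    environment_id = joined$environment_id,
    contrib = joined$rainfall_mm * o_days / m_days,
    o_days = o_days
  ) |>
    dplyr::group_by(.data$environment_id) |>
    dplyr::summarise(rain_sum = sum(.data$contrib),
                     covered_days = sum(.data$o_days), .groups = "drop") |>
    dplyr::right_join(windows, by = "environment_id") |>
    dplyr::mutate(
      rain_sum = dplyr::coalesce(.data$rain_sum, 0),
      covered_days = dplyr::coalesce(.data$covered_days, 0),
      window_days = as.numeric(.data$end - .data$start) + 1
    )
  gaps <- out$covered_days < out$window_days
  if (any(gaps)) {
    bad <- out[which(gaps)[1], ]
    have <- lubridate::floor_date(
      rainfall$month[rainfall$environment_id == bad$environment_id], "month"
    )
    need <- seq(lubridate::floor_date(bad$start, "month"),
                lubridate::floor_date(bad$end, "month"), by = "month")
    missing <- as.Date(setdiff(need, have), origin = "1970-01-01")
    abort(sprintf(
      "rainfall series for %s does not cover %s month(s): %s",
      bad$environment_id, label,
      paste(format(missing, "%Y-%m"), collapse = ", ")
    ), class = "phenoeff_coverage_error")
  }
  out[, c("environment_id", "rain_sum")]
}

#' Water input of a field environment
#'
#' Total water available to the crop, quantified as the pro-rated sum of
#' monthly rainfall from 60 days before sowing until physiological maturity
#' (mm). Partial months contribute in proportion to the days covered.
#'
#' @param dataset A [field_dataset()].
#' @return Tibble with `environment_id` and `water_input` (mm).
#' @export
water_input <- function(dataset) {
  stopifnot(inherits(dataset, "field_dataset"))
  windows <- dataset$trials |>
    dplyr::distinct(.data$environment_id, .data$sowing_date,
                    .data$maturity_date) |>
    dplyr::transmute(.data$environment_id, start = .data$sowing_date - 60,
                     end = .data$maturity_date)
  .window_sums(dataset$rainfall, windows, label = "water-input") |>
    dplyr::rename(water_input = "rain_sum")
}

#' Critical-period rainfall of a field environment
#'
#' Pro-rated rainfall (mm) between 3 months and 1 month before physiological
#' maturity — the yield-critical window used to separate dry from wet
#' environments.
#'
#' @param dataset A [field_dataset()].
#' @return Tibble with `environment_id` and `critical_rainfall` (mm).
#' @export
critical_period_rainfall <- function(dataset) {
  stopifnot(inherits(dataset, "field_dataset"))
  windows <- dataset$trials |>
    dplyr::distinct(.data$environment_id, .data$maturity_date) |>
    dplyr::transmute(
      .data$environment_id,
      start = lubridate::add_with_rollback(.data$maturity_date, -months(3)),
      end = lubridate::add_with_rollback(.data$maturity_date, -months(1))
    )
  .window_sums(dataset$rainfall, windows, label = "critical-period") |>
    dplyr::rename(critical_rainfall = "rain_sum")
}

# Saturating yield-response curve: a * (1 - exp(b * (w - c))), b < 0.
.envelope_predict <- function(a, b, c, w) a * (1 - exp(b * (w - c)))

#' Fit the yield-vs-water-input envelope curve
#'
#' Fits the boundary (envelope) function
#' `Yield = a * (1 - exp(b * (water_input - c)))` — `a` the attainable yield
#' (kg/ha), `b` the initial factor-use efficiency (1/mm, negative under the
#' saturating convention), `c` the minimum water input for any yield (mm) —
#' iteratively so that at least 95% of environments lie on or below the
#' curve. The iteration is an asymmetric-loss least squares: squared
#' residuals of points above the curve are inflated by a weight `lambda`,
#' and `lambda` is raised by bisection until the on-or-below fraction is the
#' smallest achievable fraction at or above `target_frac`. Points exactly on
#' the curve count as below.
#'
#' @param env_points Tibble with `water_input` and `mean_yield` columns, one
#'   row per environment (at least 10, spanning a range of water inputs).
#' @param target_frac Required on-or-below fraction (default 0.95).
#' @param max_iter Bisection iterations (default 60).
#' @return Object of class `envelope_fit`: list with `a`, `b`, `c`,
#'   `fraction_below`, `lambda`, `on_curve_tol` (the yield tolerance within
#'   which a point counts as lying on the curve), `n`, `trace` (tibble of
#'   the bisection path: `lambda`, `fraction_below`), and the fitting data.
#'   Supports [tidy()], [glance()], [autoplot()] and [predict()].
#' @export
fit_envelope <- function(env_points, target_frac = 0.95, max_iter = 60) {
  w <- env_points$water_input
  y <- env_points$mean_yield
  keep <- is.finite(w) & is.finite(y)
  w <- w[keep]
  y <- y[keep]
  if (length(w) < 10) {
    abort("need at least 10 environments to fit an envelope",
          class = "phenoeff_fit_error")
  }
  if (diff(range(w)) <= 0) {
    abort("degenerate water-input range", class = "phenoeff_fit_error")
  }

  # "exactly on the curve" in floating point: within a sliver of the yield
  # scale (large asymmetry weights pin points onto the curve from above by
  # an amount shrinking as 1/sqrt(lambda), never to literal zero)
  on_tol <- 1e-3 * sd(y)

  # parameters: a, log(-b), c — enforces the saturating convention b < 0;
  # -b is capped at 0.5/mm to keep the curve away from a degenerate step
  loss <- function(par, lambda) {
    if (!all(is.finite(par)) || par[2] > log(0.5)) return(1e300)
    a <- par[1]
    b <- -exp(par[2])
    c <- par[3]
    res <- y - .envelope_predict(a, b, c, w)
    wt <- ifelse(res > 0, lambda, 1) # res > 0: point above the curve
    val <- sum(wt * res^2)
    if (!is.finite(val)) 1e300 else val
  }
  frac_below <- function(par) {
    pred <- .envelope_predict(par[1], -exp(par[2]), par[3], w)
    mean(y <= pred + on_tol)
  }
  start0 <- c(max(y), log(2 / diff(range(w))), min(w) * 0.5)
  # warm starts speed the bisection up but can trap Nelder-Mead in a local
  # minimum at large asymmetry weights; always race them against a cold start
  fit_at <- function(lambda, start) {
    cands <- lapply(unique(list(start, start0)), function(s) {
      f <- optim(s, loss, lambda = lambda, method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-12))
      optim(f$par, loss, lambda = lambda, method = "Nelder-Mead",
            control = list(maxit = 3000, reltol = 1e-12))
    })
    cands[[which.min(vapply(cands, function(f) f$value, numeric(1)))]]
  }
  trace <- list()
  fit1 <- fit_at(1, start0)
  f1 <- frac_below(fit1$par)
  trace[[1]] <- c(lambda = 1, fraction_below = f1)

  if (f1 >= target_frac) {
    best <- list(lambda = 1, fit = fit1, frac = f1)
  } else {
    lo <- 1
    hi <- 2
    fit_hi <- fit_at(hi, fit1$par)
    f_hi <- frac_below(fit_hi$par)
    trace[[length(trace) + 1]] <- c(lambda = hi, fraction_below = f_hi)
    n_dbl <- 0
    while (f_hi < target_frac && n_dbl < 40) {
      lo <- hi
      hi <- hi * 2
      fit_hi <- fit_at(hi, fit_hi$par)
      f_hi <- frac_below(fit_hi$par)
      trace[[length(trace) + 1]] <- c(lambda = hi, fraction_below = f_hi)
      n_dbl <- n_dbl + 1
    }
    if (f_hi < target_frac) {
      abort("envelope fit did not reach the target on-or-below fraction",
            class = "phenoeff_fit_error")
    }
    best <- list(lambda = hi, fit = fit_hi, frac = f_hi)
    for (i in seq_len(max_iter)) {
      mid <- sqrt(lo * hi)
      fit_mid <- fit_at(mid, best$fit$par)
      f_mid <- frac_below(fit_mid$par)
      trace[[length(trace) + 1]] <- c(lambda = mid, fraction_below = f_mid)
      if (f_mid >= target_frac) {
        # keep the smallest achievable fraction >= target (ties -> smaller
        # lambda, i.e. the least distorted fit)
        if (f_mid <= best$frac) best <- list(lambda = mid, fit = fit_mid, frac = f_mid)
        hi <- mid
      } else {
        lo <- mid
      }
      if (hi / lo < 1 + 1e-3) break
    }
  }

  par <- best$fit$par
  structure(
    list(
      a = par[1], b = -exp(par[2]), c = par[3],
      fraction_below = best$frac, lambda = best$lambda,
      on_curve_tol = on_tol,
      n = length(w),
      trace = tibble::as_tibble(do.call(rbind, trace)),
      data = tibble::tibble(water_input = w, mean_yield = y)
    ),
    class = "envelope_fit"
  )
}

#' @export
print.envelope_fit <- function(x, ...) {
  cat("<envelope_fit> Yield = a * (1 - exp(b * (water - c)))\n")
  cat(sprintf("  a = %.1f kg/ha, b = %.3g /mm, c = %.1f mm\n", x$a, x$b, x$c))
  cat(sprintf("  on-or-below fraction = %.3f (lambda = %.3g, n = %d)\n",
              x$fraction_below, x$lambda, x$n))
  invisible(x)
}

#' Predict attainable yield from an envelope fit
#'
#' @param object An `envelope_fit`.
#' @param newdata Optional data frame with a `water_input` column.
#' @param ... Unused.
#' @return Predicted envelope yield, kg/ha.
#' @export
predict.envelope_fit <- function(object, newdata = NULL, ...) {
  w <- if (is.null(newdata)) object$data$water_input else newdata$water_input
  .envelope_predict(object$a, object$b, object$c, w)
}

#' Classify environments by water limitation and moisture
#'
#' An environment is water-limited when its mean yield falls within the
#' closed band of plus/minus `band` around the envelope prediction for its
#' water input; environments outside the band were limited by other factors
#' and are excluded. Water-limited environments are further classed by
#' critical-period rainfall: dry below `dry_mm`, wet at or above `2 * dry_mm`,
#' intermediate otherwise. The classification is a complete partition:
#' every environment receives exactly one of excluded/dry/intermediate/wet.
#'
#' @param envs Tibble with `environment_id`, `water_input`, `mean_yield`,
#'   `critical_rainfall`.
#' @param fit An [fit_envelope()] result.
#' @param band Half-width of the water-limited band as a fraction of the
#'   envelope prediction (default 0.20).
#' @param dry_mm Critical-period rainfall threshold for dry environments, mm
#'   (default 175; wet is at least double).
#' @return `envs` with added `predicted_envelope_yield`, `water_limited`
#'   (logical) and `moisture_class` (factor: dry/intermediate/wet/excluded).
#' @export
classify_environments <- function(envs, fit, band = 0.20, dry_mm = 175) {
  stopifnot(inherits(fit, "envelope_fit"))
  envs |>
    dplyr::mutate(
      predicted_envelope_yield =
        .envelope_predict(fit$a, fit$b, fit$c, .data$water_input),
      water_limited =
        .data$mean_yield >= (1 - band) * .data$predicted_envelope_yield &
        .data$mean_yield <= (1 + band) * .data$predicted_envelope_yield,
      moisture_class = factor(
        dplyr::case_when(
          !.data$water_limited ~ "excluded",
          .data$critical_rainfall < dry_mm ~ "dry",
          .data$critical_rainfall >= 2 * dry_mm ~ "wet",
          TRUE ~ "intermediate"
        ),
        levels = c("dry", "intermediate", "wet", "excluded")
      )
    )
}

#' Per-genotype yield drought susceptibility index
#'
#' DSI for grain yield across the trial network: a genotype's mean yield over
#' dry environments relative to its mean over wet environments, normalised by
#' the population's dry:wet reduction (unweighted means of genotype means).
#' Genotypes lacking either class are reported with `NA` and flagged.
#'
#' @param trials Tibble with `environment_id`, `genotype`, `yield`.
#' @param classes Output of [classify_environments()] (needs
#'   `environment_id`, `moisture_class`).
#' @return Tibble per genotype: `genotype`, `mean_yield_dry`,
#'   `mean_yield_wet`, `n_dry`, `n_wet`, `dsi_yield`.
#' @export
yield_dsi <- function(trials, classes) {
  cls <- classes[, c("environment_id", "moisture_class")]
  means <- trials[, c("environment_id", "genotype", "yield")] |>
    dplyr::inner_join(cls, by = "environment_id") |>
    dplyr::filter(.data$moisture_class %in% c("dry", "wet")) |>
    dplyr::group_by(.data$genotype, .data$moisture_class) |>
    dplyr::summarise(m = mean(.data$yield), n = dplyr::n_distinct(.data$environment_id),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "moisture_class",
                       values_from = c("m", "n"),
                       names_sep = "_")
  for (col in c("m_dry", "m_wet")) if (!col %in% names(means)) means[[col]] <- NA_real_
  for (col in c("n_dry", "n_wet")) if (!col %in% names(means)) means[[col]] <- 0L
  means$n_dry[is.na(means$n_dry)] <- 0L
  means$n_wet[is.na(means$n_wet)] <- 0L
  complete <- !is.na(means$m_dry) & !is.na(means$m_wet)
  x_wet <- mean(means$m_wet[complete])
  x_dry <- mean(means$m_dry[complete])
  out <- tibble::tibble(
    genotype = means$genotype,
    mean_yield_dry = means$m_dry,
    mean_yield_wet = means$m_wet,
    n_dry = means$n_dry,
    n_wet = means$n_wet,
    dsi_yield = NA_real_
  )
  if (any(complete)) {
    out$dsi_yield[complete] <- dsi(
      y_ww = means$m_wet[complete], y_wd = means$m_dry[complete],
      x_ww = x_wet, x_wd = x_dry
    )
  }
  if (any(!complete)) {
    warn(sprintf("genotype(s) without both dry and wet coverage: %s",
                 paste(out$genotype[!complete], collapse = ", ")))
  }
  out
}

#' Yield-deviation slope against water input
#'
#' For each genotype, the OLS slope of its yield deviation from the
#' environment mean (`delta_y = yield - environment mean`) on the
#' environment's water input, in kg ha^-1 mm^-1. Genotypes relatively better
#' in drier environments have negative slopes (tolerant); positive slopes
#' mark sensitivity. Genotypes observed in fewer than 3 environments are
#' reported with `NA`.
#'
#' @param trials Tibble with `environment_id`, `genotype`, `yield`.
#' @param water Tibble with `environment_id`, `water_input`.
#' @param environments Optional character vector restricting the analysis to
#'   those environments (typically the water-limited ones).
#' @return Tibble per genotype: `genotype`, `delta_y_slope`,
#'   `n_environments`.
#' @export
delta_y_slope <- function(trials, water, environments = NULL) {
  sel <- trials[, c("environment_id", "genotype", "yield")]
  if (!is.null(environments)) {
    sel <- dplyr::filter(sel, .data$environment_id %in% environments)
  }
  sel <- sel |>
    dplyr::group_by(.data$environment_id) |>
    dplyr::mutate(delta_y = .data$yield - mean(.data$yield)) |>
    dplyr::ungroup() |>
    dplyr::inner_join(water, by = "environment_id")
  sel |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      n_environments = dplyr::n_distinct(.data$environment_id),
      delta_y_slope = if (dplyr::n_distinct(.data$environment_id) < 3 ||
                          var(.data$water_input) == 0) NA_real_ else
        .ols(.data$water_input, .data$delta_y)$slope,
      .groups = "drop"
    )
}

#' Validate a platform trait against field tolerance estimates
#'
#' Final validation regression of the framework: per-genotype platform trait
#' values (e.g. transpiration efficiency at 13 DAE) regressed on a field
#' tolerance estimate (yield DSI or the delta-Y slope). A negative slope
#' means the trait marks tolerance.
#'
#' @param trait_values Tibble (`genotype`, `value`) of platform trait means.
#' @param tolerance Tibble (`genotype`, plus one of `dsi_yield` /
#'   `delta_y_slope` / `value`) of field tolerance estimates.
#' @return One-row tibble: `r2`, `p_value`, `slope`, `intercept`, `n`.
#' @export
validate_trait <- function(trait_values, tolerance) {
  tol_col <- intersect(c("dsi_yield", "delta_y_slope", "value"),
                       names(tolerance))[1]
  if (is.na(tol_col)) {
    abort("tolerance must contain dsi_yield, delta_y_slope or value",
          class = "phenoeff_domain_error")
  }
  joined <- dplyr::inner_join(
    trait_values[, c("genotype", "value")],
    setNames(tolerance[, c("genotype", tol_col)], c("genotype", "tol")),
    by = "genotype"
  )
  .ols_inference(x = joined$tol, y = joined$value)
}
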