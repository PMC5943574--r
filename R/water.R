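#' Daily transpiration from the gravimetric water balance
#'
#' One day's transpiration of a potted plant from successive pot weighings:
#' `(previous_day_weight + irrigation_added - today_weight) - evaporation -
#' plant_weight_gain`, in g d^-1. The weighing convention is post-irrigation
#' (the platform weighs after watering); `plant_weight_gain` is the
#' interpolated daily fresh-weight gain from the weekly calibration harvests.
#' Negative balances (weighing noise) clamp to zero by default; the raw value
#' is returned alongside so audits can retain it.
#'
#' @param weight_prev Previous day's (post-irrigation) pot weight, g.
#' @param weight_today Today's pot weight, g.
#' @param irrigation_added Water added since the previous weighing, g.
#' @param evaporation Soil evaporation estimate for the day, g d^-1.
#' @param plant_weight_gain Plant fresh-weight gain for the day, g d^-1.
#' @param clamp Clamp negative balances at zero (default `TRUE`).
#' @return Tibble with `transpiration` (possibly clamped), `raw` (unclamped
#'   balance) and `clamped` (logical).
#' @export
daily_transpiration <- function(weight_prev, weight_today, irrigation_added,
                                evaporation = 0, plant_weight_gain = 0,
                                clamp = TRUE) {
  raw <- (weight_prev + irrigation_added - weight_today) -
    evaporation - plant_weight_gain
  out <- raw
  clamped <- !is.na(raw) & raw < 0 & clamp
  out[clamped] <- 0
  tibble::tibble(transpiration = out, raw = raw, clamped = clamped)
}

#' Per-day soil evaporation from plantless control pots
#'
#' Mean daily water loss across the plantless control pots, one estimate per
#' day. Days with plant observations but no control reading reuse the most
#' recent available estimate and are flagged.
#'
#' @param controls Tibble with `dae` and `evaporation` (g lost per control pot
#'   that day); multiple pots per day are averaged.
#' @param days Integer vector of days an estimate is needed for (defaults to
#'   the observed control days).
#' @return Tibble with `dae`, `evaporation` (g d^-1) and `carried_forward`
#'   (logical flag for gap-filled days).
#' @export
evaporation_estimate <- function(controls, days = NULL) {
  controls <- tibble::as_tibble(controls)
  .assert_cols(controls, c("dae", "evaporation"), "evaporation controls")
  daily <- controls |>
    dplyr::group_by(dae = .data$dae) |>
    dplyr::summarise(evaporation = mean(.data$evaporation), .groups = "drop") |>
    dplyr::arrange(.data$dae)
  if (nrow(daily) == 0) {
    abort("no evaporation controls supplied", class = "phenoeff_domain_error")
  }
  if (is.null(days)) days <- daily$dae
  days <- sort(unique(days))
  idx <- findInterval(days, daily$dae)
  carried <- !(days %in% daily$dae)
  idx[idx == 0] <- 1 # days before the first control borrow the first estimate
  tibble::tibble(
    dae = days,
    evaporation = daily$evaporation[idx],
    carried_forward = carried
  )
}

#' Daily plant fresh-weight gain from weekly calibration harvests
#'
#' Linear interpolation of plant fresh weight between weekly calibration
#' points; the daily gain is the successive difference of the interpolated
#' series (constant within each calibration interval). With fewer than two
#' calibration points the correction is zero, flagged.
#'
#' @param calibration Tibble with `dae` and `fresh_weight` (g).
#' @param days Integer vector of days a gain is needed for.
#' @return Tibble with `dae`, `gain` (g d^-1) and `flagged` (logical,
#'   `TRUE` when the zero-correction fallback applied).
#' @export
plant_weight_correction <- function(calibration, days) {
  calibration <- tibble::as_tibble(calibration)
  days <- sort(unique(days))
  if (nrow(calibration) < 2) {
    return(tibble::tibble(dae = days, gain = 0, flagged = TRUE))
  }
  calibration <- dplyr::arrange(calibration, .data$dae)
  fw <- approx(calibration$dae, calibration$fresh_weight, xout = c(days - 1, days),
               rule = 2)$y
  n <- length(days)
  tibble::tibble(dae = days, gain = fw[(n + 1):(2 * n)] - fw[1:n],
                 flagged = FALSE)
}

#' Transpiration efficiency
#'
#' Shoot dry mass produced per unit of water transpired, accumulated from
#' emergence: `1000 * sdw / cumulative_transpiration`, in g dry mass per kg
#' water. Undefined (NA) when no water has been transpired.
#'
#' @param sdw Shoot dry weight, g.
#' @param cumulative_transpiration Water transpired from 0 DAE to the
#'   measurement day, g.
#' @return TE in g kg^-1 (vectorised).
#' @export
#' @examples
#' transpiration_efficiency(0.5, 140) # ~3.57 g/kg
transpiration_efficiency <- function(sdw, cumulative_transpiration) {
  ifelse(
    is.na(cumulative_transpiration) | cumulative_transpiration <= 0,
    NA_real_,
    1000 * sdw / cumulative_transpiration
  )
}

#' Transpiration rate per unit leaf area
#'
#' Converts a mass of water transpired over a timed interval on a known leaf
#' area to mg m^-2 s^-1 (the unit used for transpiration-rate response
#' curves): `1000 * grams / (leaf_area_cm2 / 1e4) / seconds`.
#'
#' @param transpiration Water transpired during the interval, g.
#' @param leaf_area Leaf area, cm2 (> 0).
#' @param interval Interval length, s (> 0).
#' @return TR in mg m^-2 s^-1 (vectorised; `NA` where leaf area is 0/NA).
#' @export
transpiration_rate_per_area <- function(transpiration, leaf_area, interval) {
  if (any(interval <= 0, na.rm = TRUE)) {
    abort("interval must be positive", class = "phenoeff_domain_error")
  }
  ifelse(
    is.na(leaf_area) | leaf_area <= 0,
    NA_real_,
    (transpiration * 1000) / (leaf_area / 1e4) / interval
  )
}
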