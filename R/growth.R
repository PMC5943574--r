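#' Estimate shoot dry weight from leaf area and plant age
#'
#' Platform calibration relating shoot dry weight (g) to leaf area (cm2) and
#' plant age (days after emergence):
#' `SDW = c0 + c1 * LA + c2 * LA * age`. The default coefficients are the
#' GlyPh soybean calibration; they are a platform property and should be
#' recalibrated for other platforms or species.
#'
#' @param leaf_area Leaf area in cm2 (vectorised).
#' @param plant_age Plant age in days after emergence (vectorised).
#' @param coef Numeric vector of the three calibration coefficients
#'   (intercept, leaf-area term, leaf-area-by-age term).
#' @return Shoot dry weight in g.
#' @export
#' @examples
#' estimate_sdw(100, 20) # 0.4692
estimate_sdw <- function(leaf_area, plant_age,
                         coef = c(0.1, 0.00184, 0.0000926)) {
  if (any(leaf_area < 0, na.rm = TRUE) || any(plant_age < 0, na.rm = TRUE)) {
    abort("leaf_area and plant_age must be >= 0", class = "phenoeff_domain_error")
  }
  stopifnot(length(coef) == 3)
  coef[1] + coef[2] * leaf_area + coef[3] * leaf_area * plant_age
}

#' Leaf area from terminal-leaflet dimensions
#'
#' Total leaf area as `k * width * length` summed over leaflets. The
#' shape coefficient `k` is a species calibration and has no default: it must
#' be supplied explicitly whenever leaflet dimensions are the input.
#'
#' @param width,length Leaflet width(s) and length(s) in cm.
#' @param k Dimensionless leaflet-shape coefficient (> 0), user-supplied.
#' @return Leaf area in cm2 (summed over the supplied leaflets).
#' @export
leaf_area_from_leaflets <- function(width, length, k) {
  if (missing(k) || is.null(k)) {
    abort("leaflet-shape coefficient k must be supplied (no default)",
          class = "phenoeff_config_error")
  }
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    abort("k must be a single positive number", class = "phenoeff_config_error")
  }
  if (any(width < 0, na.rm = TRUE) || any(length < 0, na.rm = TRUE)) {
    abort("leaflet dimensions must be >= 0", class = "phenoeff_domain_error")
  }
  sum(k * width * length)
}

#' Relative expansion rate of leaf area
#'
#' Classical growth-analysis RER over an interval:
#' `(ln LA2 - ln LA1) / (t2 - t1)`, in d^-1.
#'
#' @param la1,la2 Leaf area (cm2) at the start and end of the interval; must
#'   be positive.
#' @param t1,t2 Times in days; `t2 > t1`.
#' @return RER in d^-1 (vectorised).
#' @export
relative_expansion_rate <- function(la1, la2, t1, t2) {
  if (any(t2 <= t1, na.rm = TRUE)) {
    abort("t2 must be greater than t1", class = "phenoeff_domain_error")
  }
  if (any(la1 <= 0, na.rm = TRUE) || any(la2 <= 0, na.rm = TRUE)) {
    abort("leaf areas must be positive", class = "phenoeff_domain_error")
  }
  (log(la2) - log(la1)) / (t2 - t1)
}

#' Net assimilation rate over an interval
#'
#' Mean rate of dry-mass gain per unit leaf area, in g cm^-2 d^-1. The
#' default `classical` form is the standard growth-analysis expression
#' `(dSDW/dt) * (dlnLA/dLA)`, whose bracket degenerates to `1/LA` when leaf
#' area does not change (its analytic limit). The `as_printed` variant divides
#' by the log-area bracket instead of multiplying; it is dimensionally a
#' different quantity and is retained only for auditing analyses that used
#' that form.
#'
#' @param sdw1,sdw2 Shoot dry weight (g) at the interval ends.
#' @param la1,la2 Leaf area (cm2) at the interval ends; positive.
#' @param t1,t2 Times in days; `t2 > t1`.
#' @param formula `"classical"` (default) or `"as_printed"`.
#' @return NAR (vectorised).
#' @export
net_assimilation_rate <- function(sdw1, sdw2, la1, la2, t1, t2,
                                  formula = c("classical", "as_printed")) {
  formula <- match.arg(formula)
  if (any(t2 <= t1, na.rm = TRUE)) {
    abort("t2 must be greater than t1", class = "phenoeff_domain_error")
  }
  if (any(la1 <= 0, na.rm = TRUE) || any(la2 <= 0, na.rm = TRUE)) {
    abort("leaf areas must be positive", class = "phenoeff_domain_error")
  }
  rate <- (sdw2 - sdw1) / (t2 - t1)
  bracket <- ifelse(la2 == la1, 1 / la1, (log(la2) - log(la1)) / (la2 - la1))
  if (formula == "classical") rate * bracket else rate / bracket
}

#' Allometric and area-per-mass indices at harvest
#'
#' Partitioning ratios from a harvest record and the plant leaf area at
#' harvest: leaf and stem mass ratios (whole plant and branches-only) as
#' fractions of shoot dry mass (`shoot = leaf_dw + stem_dw`), specific leaf
#' area (`LA / leaf_dw`) and leaf area ratio (`LA / shoot`). Ratios with a
#' zero denominator are reported as `NA`, not as errors, so downstream
#' regressions drop them explicitly.
#'
#' @param harvest One-row data frame (or list) with `leaf_dw`, `stem_dw`,
#'   `leaf_dw_branches`, `stem_dw_branches` in g.
#' @param leaf_area Plant leaf area at harvest, cm2 (optional; `NA` skips
#'   SLA/LAR).
#' @return One-row tibble with `lmr`, `smr`, `lmr_b`, `smr_b`, `sla`, `lar`.
#' @export
growth_indices_at_harvest <- function(harvest, leaf_area = NA_real_) {
  leaf <- harvest$leaf_dw
  stem <- harvest$stem_dw
  leaf_b <- harvest$leaf_dw_branches %||% 0
  stem_b <- harvest$stem_dw_branches %||% 0
  shoot <- leaf + stem
  safe_div <- function(num, den) ifelse(is.na(den) | den <= 0, NA_real_, num / den)
  tibble::tibble(
    lmr = safe_div(leaf, shoot),
    smr = safe_div(stem, shoot),
    lmr_b = safe_div(leaf_b, shoot),
    smr_b = safe_div(stem_b, shoot),
    sla = safe_div(leaf_area, leaf),
    lar = safe_div(leaf_area, shoot)
  )
}

#' Leaf-to-air temperature difference
#'
#' Mean of the measured leaf temperatures minus air temperature (degC).
#' Thermal protocols read two top fully-expanded leaves and average them; a
#' single reading degrades gracefully to that reading.
#'
#' @param leaf_temps Numeric vector of leaf temperature readings, degC.
#' @param air_temp Air temperature, degC.
#' @return Temperature difference in degC; `NA` when no leaf reading exists.
#' @export
leaf_air_temperature_difference <- function(leaf_temps, air_temp) {
  leaf_temps <- leaf_temps[!is.na(leaf_temps)]
  if (length(leaf_temps) == 0 || is.na(air_temp)) return(NA_real_)
  mean(leaf_temps) - air_temp
}
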