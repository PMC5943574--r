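#' Per-plant transpiration series from daily pot weighings
#'
#' Recovers daily transpiration for every plant from the gravimetric water
#' balance: successive post-irrigation pot weights, irrigation added, the
#' per-day soil-evaporation estimate from the plantless control pots, and the
#' daily plant fresh-weight gain interpolated from the weekly calibration
#' harvests (when the dataset carries a `calibration` table; otherwise the
#' correction is zero). Negative balances clamp to zero with the raw value
#' kept in an audit column.
#'
#' @param dataset A [platform_dataset()].
#' @param clamp Clamp negative daily balances at zero (default `TRUE`).
#' @return Tibble with `plant_id`, `genotype`, `treatment`, `replicate`,
#'   `dae`, `transpiration` (g/d), `raw`, `clamped`, and `cumulative` (g
#'   transpired from 0 DAE, missing days contributing zero).
#' @export
compute_transpiration <- function(dataset, clamp = TRUE) {
  stopifnot(inherits(dataset, "platform_dataset"))
  plants <- dataset$plants |>
    dplyr::filter(!is.na(.data$pot_weight)) |>
    dplyr::arrange(.data$plant_id, .data$dae)
  if (nrow(plants) == 0) {
    return(tibble::tibble(
      plant_id = character(), genotype = character(), treatment = character(),
      replicate = integer(), dae = integer(), transpiration = double(),
      raw = double(), clamped = logical(), cumulative = double()
    ))
  }
  evap <- evaporation_estimate(dataset$evaporation, days = unique(plants$dae))

  gain_tbl <- NULL
  if (!is.null(dataset$calibration) && nrow(dataset$calibration) > 0) {
    gain_tbl <- dataset$calibration |>
      dplyr::group_by(.data$treatment) |>
      dplyr::group_modify(~ plant_weight_correction(.x, days = unique(plants$dae))) |>
      dplyr::ungroup()
  }

  out <- plants |>
    dplyr::group_by(.data$plant_id, .data$genotype, .data$treatment,
                    .data$replicate) |>
    dplyr::mutate(
      prev_weight = dplyr::lag(.data$pot_weight),
      prev_dae = dplyr::lag(.data$dae),
      consecutive = !is.na(.data$prev_dae) & .data$dae - .data$prev_dae == 1
    ) |>
    dplyr::ungroup() |>
    dplyr::left_join(evap[, c("dae", "evaporation")], by = "dae")
  if (is.null(gain_tbl)) {
    out$gain <- 0
  } else {
    out <- out |>
      dplyr::left_join(gain_tbl[, c("treatment", "dae", "gain")],
                       by = c("treatment", "dae")) |>
      dplyr::mutate(gain = dplyr::coalesce(.data$gain, 0))
  }
  balance <- daily_transpiration(
    weight_prev = out$prev_weight,
    weight_today = out$pot_weight,
    irrigation_added = dplyr::coalesce(out$irrigation_added, 0),
    evaporation = dplyr::coalesce(out$evaporation, 0),
    plant_weight_gain = out$gain,
    clamp = clamp
  )
  out$transpiration <- ifelse(out$consecutive, balance$transpiration, NA_real_)
  out$raw <- ifelse(out$consecutive, balance$raw, NA_real_)
  out$clamped <- out$consecutive & balance$clamped
  out |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::mutate(cumulative = cumsum(dplyr::coalesce(.data$transpiration, 0))) |>
    dplyr::ungroup() |>
    dplyr::select("plant_id", "genotype", "treatment", "replicate", "dae",
                  "transpiration", "raw", "clamped", "cumulative")
}

#' Extract the trait-observation table from a platform experiment
#'
#' Computes the full battery of morphology, growth, water-use and temperature
#' traits from a platform dataset and returns them in the atomic long format
#' scored by the selection framework: one row per
#' (trait, dae, treatment, genotype, replicate). Traits emitted (where the
#' underlying measurements exist):
#'
#' * `Leaf area` (cm2) and `Shoot dry weight` (g, via [estimate_sdw()]) on
#'   every day leaf area was measured; `LAR` (cm2/g) on the same days.
#' * `RER` (1/d) and `NAR` (g cm-2 d-1, classical form) over successive
#'   leaf-area measurement intervals, reported at the interval's end day.
#' * `Transpiration (T)` (g/d) daily; `TE` (g/kg) on leaf-area days;
#'   `Total transpired water` (g) and `Transpired water during WS` (g) at the
#'   final day.
#' * Harvest traits at the harvest day: `Leaf dry weight`, `Stem dry weight`,
#'   `LMR`, `SMR`, `LMR_b`, `SMR_b`, `SLA`, `Number of nodes`,
#'   `Number of branches`.
#' * `Leaf temperature`, `Leaf-to-Air temperature difference` (degC) and
#'   `Stomatal conductance (gs)` on their measurement days.
#'
#' @param dataset A [platform_dataset()].
#' @param sdw_coef Calibration coefficients passed to [estimate_sdw()].
#' @param nar_formula Passed to [net_assimilation_rate()].
#' @return Tibble of trait observations with columns `trait`, `dae`,
#'   `treatment`, `genotype`, `replicate`, `value`.
#' @export
platform_traits <- function(dataset,
                            sdw_coef = c(0.1, 0.00184, 0.0000926),
                            nar_formula = "classical") {
  stopifnot(inherits(dataset, "platform_dataset"))
  plants <- dataset$plants
  onset <- dataset$treatment_onset_dae
  id_cols <- c("genotype", "treatment", "replicate")

  obs_row <- function(df, trait, value) {
    tibble::tibble(
      trait = trait, dae = as.integer(df$dae),
      treatment = df$treatment, genotype = df$genotype,
      replicate = as.integer(df$replicate), value = value
    )
  }
  pieces <- list()

  la <- plants |>
    dplyr::filter(!is.na(.data$leaf_area)) |>
    dplyr::arrange(.data$plant_id, .data$dae)
  if (nrow(la) > 0) {
    sdw <- estimate_sdw(la$leaf_area, la$dae, coef = sdw_coef)
    pieces$la <- obs_row(la, "Leaf area", la$leaf_area)
    pieces$sdw <- obs_row(la, "Shoot dry weight", sdw)
    pieces$lar <- obs_row(la, "LAR", ifelse(sdw > 0, la$leaf_area / sdw, NA_real_))

    ivals <- la |>
      dplyr::mutate(sdw = sdw) |>
      dplyr::group_by(.data$plant_id) |>
      dplyr::mutate(
        la1 = dplyr::lag(.data$leaf_area), t1 = dplyr::lag(.data$dae),
        sdw1 = dplyr::lag(.data$sdw)
      ) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$la1), .data$la1 > 0, .data$leaf_area > 0)
    if (nrow(ivals) > 0) {
      pieces$rer <- obs_row(
        ivals, "RER",
        relative_expansion_rate(ivals$la1, ivals$leaf_area, ivals$t1, ivals$dae)
      )
      pieces$nar <- obs_row(
        ivals, "NAR",
        net_assimilation_rate(ivals$sdw1, ivals$sdw, ivals$la1,
                              ivals$leaf_area, ivals$t1, ivals$dae,
                              formula = nar_formula)
      )
    }
  }

  tr <- compute_transpiration(dataset)
  if (nrow(tr) > 0) {
    tr_obs <- dplyr::filter(tr, !is.na(.data$transpiration))
    pieces$t_daily <- obs_row(tr_obs, "Transpiration (T)", tr_obs$transpiration)
    if (nrow(la) > 0) {
      te_in <- la |>
        dplyr::mutate(sdw = estimate_sdw(.data$leaf_area, .data$dae,
                                         coef = sdw_coef)) |>
        dplyr::inner_join(tr[, c("plant_id", "dae", "cumulative")],
                          by = c("plant_id", "dae"))
      pieces$te <- obs_row(
        te_in, "TE",
        transpiration_efficiency(te_in$sdw, te_in$cumulative)
      )
    }
    finals <- tr |>
      dplyr::arrange(.data$plant_id, .data$dae) |>
      dplyr::group_by(.data$plant_id, .data$genotype, .data$treatment,
                      .data$replicate) |>
      dplyr::summarise(
        total = dplyr::last(.data$cumulative),
        ws = sum(.data$transpiration[.data$dae > onset], na.rm = TRUE),
        dae = max(.data$dae),
        .groups = "drop"
      )
    pieces$total_t <- obs_row(finals, "Total transpired water", finals$total)
    if (!is.na(onset)) {
      pieces$ws_t <- obs_row(finals, "Transpired water during WS", finals$ws)
    }
  }

  if (nrow(dataset$harvests) > 0) {
    hv <- dataset$harvests |>
      dplyr::inner_join(
        dplyr::distinct(plants, .data$plant_id, .data$genotype,
                        .data$treatment, .data$replicate),
        by = "plant_id"
      ) |>
      dplyr::left_join(
        dplyr::select(la, "plant_id", "dae", la_h = "leaf_area"),
        by = c("plant_id", "dae")
      )
    idx <- growth_indices_at_harvest(hv, leaf_area = hv$la_h)
    pieces$harvest <- dplyr::bind_rows(
      obs_row(hv, "Leaf dry weight", hv$leaf_dw),
      obs_row(hv, "Stem dry weight", hv$stem_dw),
      obs_row(hv, "LMR", idx$lmr),
      obs_row(hv, "SMR", idx$smr),
      obs_row(hv, "LMR_b", idx$lmr_b),
      obs_row(hv, "SMR_b", idx$smr_b),
      obs_row(hv, "SLA", idx$sla),
      if ("n_nodes" %in% names(hv)) {
        obs_row(hv, "Number of nodes", as.numeric(hv$n_nodes))
      },
      if ("n_branches" %in% names(hv)) {
        obs_row(hv, "Number of branches", as.numeric(hv$n_branches))
      }
    )
  }

  temps <- dplyr::filter(plants, !is.na(.data$leaf_temp))
  if (nrow(temps) > 0) {
    pieces$leaf_temp <- obs_row(temps, "Leaf temperature", temps$leaf_temp)
    dt <- dplyr::filter(temps, !is.na(.data$air_temp))
    if (nrow(dt) > 0) {
      pieces$leaf_dt <- obs_row(dt, "Leaf-to-Air temperature difference",
                                dt$leaf_temp - dt$air_temp)
    }
  }
  gs <- dplyr::filter(plants, !is.na(.data$gs))
  if (nrow(gs) > 0) {
    pieces$gs <- obs_row(gs, "Stomatal conductance (gs)", gs$gs)
  }

  out <- dplyr::bind_rows(pieces) |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::arrange(.data$trait, .data$dae, .data$treatment, .data$genotype,
                   .data$replicate)
  out
}
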