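#' Assemble a platform dataset
#'
#' Bundles the three relations produced by a greenhouse phenotyping platform
#' run — per-plant daily records, end-of-experiment harvest records, and
#' plantless-pot evaporation controls — together with the experiment metadata
#' that downstream trait computations need (the day the water-deficit
#' treatment started, on the days-after-emergence axis).
#'
#' Row-level validation is total: every input row is either kept or rejected
#' with exactly one diagnostic. Rejected rows are dropped from the dataset and
#' reported in the `diagnostics` element.
#'
#' @param plants Tibble of per-plant daily records with columns `plant_id`,
#'   `genotype`, `treatment`, `replicate`, `dae` and any of the optional
#'   measurement columns `leaf_area` (cm2), `pot_weight` (g),
#'   `irrigation_added` (g), `leaf_temp` (degC), `air_temp` (degC), `gs`
#'   (porometer units, carried opaquely), `vpd` (kPa).
#' @param harvests Tibble of harvest records: `plant_id`, `dae`, `leaf_dw`,
#'   `stem_dw`, `leaf_dw_branches`, `stem_dw_branches` (g), `n_nodes`,
#'   `n_branches`. May be empty.
#' @param evaporation Tibble of per-day soil evaporation controls:
#'   `dae`, `pot_id`, `evaporation` (g lost that day by a plantless pot).
#' @param calibration Optional tibble of weekly fresh-weight calibration
#'   harvests used for the plant-weight correction of the water balance:
#'   `treatment`, `dae`, `fresh_weight` (g).
#' @param treatment_onset_dae Integer day after emergence at which the
#'   water-deficit treatment was imposed.
#' @param experiment_id Label for the run.
#'
#' @return An object of class `platform_dataset`: a list with elements
#'   `plants`, `harvests`, `evaporation` (validated tibbles),
#'   `treatment_onset_dae`, `experiment_id`, and `diagnostics` (tibble of
#'   rejected rows, zero rows when everything validated).
#' @export
platform_dataset <- function(plants,
                             harvests = NULL,
                             evaporation = NULL,
                             calibration = NULL,
                             treatment_onset_dae = NA_integer_,
                             experiment_id = "experiment") {
  plants <- tibble::as_tibble(plants)
  .assert_cols(plants, c("plant_id", "genotype", "treatment", "dae"), "plants")
  if (!"replicate" %in% names(plants)) plants$replicate <- 1L
  plants$dae <- as.integer(plants$dae)
  plants$replicate <- as.integer(plants$replicate)
  optional <- c(
    "leaf_area", "pot_weight", "irrigation_added",
    "leaf_temp", "air_temp", "gs", "vpd"
  )
  for (col in optional) {
    # all-NA columns read back from CSV arrive as logical; store as numeric
    plants[[col]] <- as.numeric(plants[[col]] %||% NA_real_)
  }

  diags <- list()
  bad <- rep(FALSE, nrow(plants))

  flag <- function(idx, field, msg) {
    fresh <- idx & !bad
    if (any(fresh)) {
      diags[[length(diags) + 1]] <<- .diag_row("plants", which(fresh), field, msg)
      bad <<- bad | fresh
    }
  }
  flag(!is.finite(plants$dae) | plants$dae < 0, "dae", "dae must be >= 0")
  flag(!is.na(plants$leaf_area) & plants$leaf_area < 0,
       "leaf_area", "leaf_area must be >= 0 when present")
  flag(!is.na(plants$pot_weight) & plants$pot_weight <= 0,
       "pot_weight", "pot_weight must be > 0 when present")

  # duplicate (plant_id, dae) with conflicting measurements is an integrity
  # error, not a row rejection
  key <- paste(plants$plant_id, plants$dae)
  if (anyDuplicated(key[!bad])) {
    dup_keys <- unique(key[!bad][duplicated(key[!bad])])
    conflict <- vapply(dup_keys, function(k) {
      rows <- plants[!bad & key == k, optional, drop = FALSE]
      any(vapply(rows, function(v) length(unique(v[!is.na(v)])) > 1, logical(1)))
    }, logical(1))
    if (any(conflict)) {
      abort(sprintf(
        "conflicting duplicate (plant_id, dae) record(s): %s",
        paste(dup_keys[conflict], collapse = "; ")
      ), class = "phenoeff_integrity_error")
    }
    # non-conflicting duplicates collapse to the first occurrence
    bad <- bad | (duplicated(key) & !bad[match(key, key)])
  }

  plants_ok <- plants[!bad, , drop = FALSE]

  if (is.null(harvests) || nrow(tibble::as_tibble(harvests)) == 0) {
    harvests <- tibble::tibble(
      plant_id = character(), dae = integer(),
      leaf_dw = double(), stem_dw = double(),
      leaf_dw_branches = double(), stem_dw_branches = double(),
      n_nodes = integer(), n_branches = integer()
    )
  } else {
    harvests <- tibble::as_tibble(harvests)
    .assert_cols(harvests, c("plant_id", "dae", "leaf_dw", "stem_dw"), "harvests")
    harvests$dae <- as.integer(harvests$dae)
    for (col in c("leaf_dw_branches", "stem_dw_branches")) {
      if (!col %in% names(harvests)) harvests[[col]] <- 0
    }
    hbad <- rep(FALSE, nrow(harvests))
    hflag <- function(idx, field, msg) {
      fresh <- idx & !hbad
      if (any(fresh)) {
        diags[[length(diags) + 1]] <<- .diag_row("harvests", which(fresh), field, msg)
        hbad <<- hbad | fresh
      }
    }
    mass_cols <- c("leaf_dw", "stem_dw", "leaf_dw_branches", "stem_dw_branches")
    for (col in mass_cols) {
      hflag(!is.na(harvests[[col]]) & harvests[[col]] < 0, col, "mass must be >= 0")
    }
    hflag(harvests$leaf_dw_branches > harvests$leaf_dw,
          "leaf_dw_branches", "branch leaf mass exceeds total leaf mass")
    hflag(harvests$stem_dw_branches > harvests$stem_dw,
          "stem_dw_branches", "branch stem mass exceeds total stem mass")
    hflag(!harvests$plant_id %in% plants_ok$plant_id,
          "plant_id", "harvested plant_id absent from plants")
    harvests <- harvests[!hbad, , drop = FALSE]
  }

  if (is.null(evaporation)) {
    evaporation <- tibble::tibble(dae = integer(), pot_id = character(),
                                  evaporation = double())
  } else {
    evaporation <- tibble::as_tibble(evaporation)
    .assert_cols(evaporation, c("dae", "evaporation"), "evaporation")
    if (!"pot_id" %in% names(evaporation)) evaporation$pot_id <- "control"
  }

  if (is.null(calibration)) {
    calibration <- tibble::tibble(treatment = character(), dae = integer(),
                                  fresh_weight = double())
  } else {
    calibration <- tibble::as_tibble(calibration)
    .assert_cols(calibration, c("treatment", "dae", "fresh_weight"),
                 "calibration")
  }

  structure(
    list(
      plants = plants_ok,
      harvests = harvests,
      evaporation = evaporation,
      calibration = calibration,
      treatment_onset_dae = as.integer(treatment_onset_dae),
      experiment_id = experiment_id,
      diagnostics = if (length(diags)) dplyr::bind_rows(diags) else
        tibble::tibble(table = character(), row = integer(),
                       field = character(), message = character())
    ),
    class = "platform_dataset"
  )
}

#' @export
print.platform_dataset <- function(x, ...) {
  cat("<platform_dataset> ", x$experiment_id, "\n", sep = "")
  cat("  plants:      ", nrow(x$plants), " daily records, ",
      dplyr::n_distinct(x$plants$plant_id), " plants, ",
      dplyr::n_distinct(x$plants$genotype), " genotypes\n", sep = "")
  cat("  harvests:    ", nrow(x$harvests), " records\n", sep = "")
  cat("  evaporation: ", nrow(x$evaporation), " control readings\n", sep = "")
  cat("  treatment onset: ", x$treatment_onset_dae, " DAE\n", sep = "")
  if (nrow(x$diagnostics)) {
    cat("  diagnostics: ", nrow(x$diagnostics), " rejected row(s)\n", sep = "")
  }
  invisible(x)
}

#' Assemble a field trial-network dataset
#'
#' Couples the two relations of a multi-environment trial network: per-plot
#' yields (one row per environment x genotype) and monthly rainfall series per
#' environment. Environments are location-by-year combinations.
#'
#' @param trials Tibble with columns `environment_id`, `genotype`, `yield`
#'   (kg/ha), `sowing_date`, `emergence_date`, `maturity_date` (ISO-8601
#'   dates or `Date`).
#' @param rainfall Tibble with columns `environment_id`, `month` (first day of
#'   month, ISO-8601 or `Date`), `rainfall_mm`.
#'
#' @return Object of class `field_dataset`: list with validated `trials` and
#'   `rainfall` tibbles plus a `diagnostics` tibble. Environments represented
#'   by a single genotype are kept but flagged in the diagnostics, because
#'   their environment mean collapses to that genotype's yield.
#' @export
field_dataset <- function(trials, rainfall) {
  trials <- tibble::as_tibble(trials)
  rainfall <- tibble::as_tibble(rainfall)
  .assert_cols(trials, c("environment_id", "genotype", "yield",
                         "sowing_date", "emergence_date", "maturity_date"),
               "trials")
  .assert_cols(rainfall, c("environment_id", "month", "rainfall_mm"), "rainfall")

  for (col in c("sowing_date", "emergence_date", "maturity_date")) {
    parsed <- as.Date(as.character(trials[[col]]), format = "%Y-%m-%d")
    if (anyNA(parsed) && !all(is.na(trials[[col]]))) {
      abort(sprintf("unparseable %s in trials row(s): %s", col,
                    paste(which(is.na(parsed)), collapse = ", ")),
            class = "phenoeff_schema_error")
    }
    trials[[col]] <- parsed
  }
  rainfall$month <- as.Date(as.character(rainfall$month))

  diags <- list()
  bad <- !is.finite(trials$yield) | trials$yield < 0
  if (any(bad)) {
    diags[[length(diags) + 1]] <-
      .diag_row("trials", which(bad), "yield", "yield must be >= 0")
  }
  mat_bad <- !bad & trials$maturity_date <= trials$sowing_date
  if (any(mat_bad)) {
    diags[[length(diags) + 1]] <-
      .diag_row("trials", which(mat_bad), "maturity_date",
                "maturity_date must be after sowing_date")
    bad <- bad | mat_bad
  }
  trials <- trials[!bad, , drop = FALSE]

  rbad <- !is.finite(rainfall$rainfall_mm) | rainfall$rainfall_mm < 0
  if (any(rbad)) {
    diags[[length(diags) + 1]] <-
      .diag_row("rainfall", which(rbad), "rainfall_mm", "rainfall must be >= 0")
    rainfall <- rainfall[!rbad, , drop = FALSE]
  }

  singletons <- trials |>
    dplyr::count(.data$environment_id) |>
    dplyr::filter(.data$n == 1)
  if (nrow(singletons)) {
    diags[[length(diags) + 1]] <- tibble::tibble(
      table = "trials", row = NA_integer_, field = "environment_id",
      message = sprintf(
        "environment %s has a single genotype; its mean is that genotype's yield",
        singletons$environment_id
      )
    )
  }

  structure(
    list(
      trials = trials,
      rainfall = rainfall,
      diagnostics = if (length(diags)) dplyr::bind_rows(diags) else
        tibble::tibble(table = character(), row = integer(),
                       field = character(), message = character())
    ),
    class = "field_dataset"
  )
}

#' @export
print.field_dataset <- function(x, ...) {
  cat("<field_dataset>\n")
  cat("  trials:   ", nrow(x$trials), " rows, ",
      dplyr::n_distinct(x$trials$environment_id), " environments, ",
      dplyr::n_distinct(x$trials$genotype), " genotypes\n", sep = "")
  cat("  rainfall: ", nrow(x$rainfall), " monthly records\n", sep = "")
  invisible(x)
}
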