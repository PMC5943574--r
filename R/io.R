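#' Read a platform experiment from CSV files
#'
#' Reads the tidy-CSV representation of a platform experiment from a
#' directory: `plants.csv` (one row per plant per day), optional
#' `harvests.csv` and `evaporation.csv`, and `meta.yaml` holding
#' `treatment_onset_dae` and `experiment_id`. Column names can be remapped via
#' `schema`, so files produced by other platforms can be ingested without
#' rewriting.
#'
#' @param path Directory containing the CSV files.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the files, e.g.
#'   `c(plant_id = "pot", leaf_area = "LA_cm2")`.
#'
#' @return A validated [platform_dataset()]. Rows violating invariants are
#'   rejected and reported in `$diagnostics`.
#' @export
read_platform_csv <- function(path, schema = NULL) {
  if (!dir.exists(path)) {
    abort(sprintf("platform dataset directory not found: %s", path),
          class = "phenoeff_io_error")
  }
  plants_file <- file.path(path, "plants.csv")
  if (!file.exists(plants_file)) {
    abort("plants.csv not found in platform dataset directory",
          class = "phenoeff_io_error")
  }
  remap <- function(df) {
    if (is.null(schema)) return(df)
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(df) && !canon %in% names(df)) {
        names(df)[names(df) == schema[[canon]]] <- canon
      }
    }
    df
  }
  read_quiet <- function(f) {
    readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  }
  plants <- remap(read_quiet(plants_file))
  harvests <- NULL
  if (file.exists(file.path(path, "harvests.csv"))) {
    harvests <- remap(read_quiet(file.path(path, "harvests.csv")))
  }
  evaporation <- NULL
  if (file.exists(file.path(path, "evaporation.csv"))) {
    evaporation <- remap(read_quiet(file.path(path, "evaporation.csv")))
  }
  calibration <- NULL
  if (file.exists(file.path(path, "calibration.csv"))) {
    calibration <- remap(read_quiet(file.path(path, "calibration.csv")))
  }
  onset <- NA_integer_
  experiment_id <- basename(path)
  meta_file <- file.path(path, "meta.yaml")
  if (file.exists(meta_file)) {
    meta <- yaml::read_yaml(meta_file)
    onset <- meta$treatment_onset_dae %||% NA_integer_
    experiment_id <- meta$experiment_id %||% experiment_id
  }
  platform_dataset(plants, harvests, evaporation, calibration,
                   treatment_onset_dae = onset,
                   experiment_id = experiment_id)
}

#' Write a platform experiment to CSV files
#'
#' Inverse of [read_platform_csv()]: writes `plants.csv`, `harvests.csv`,
#' `evaporation.csv` and `meta.yaml` into `path`. Reading the written
#' directory back yields a dataset equal field-for-field to the input.
#'
#' @param dataset A [platform_dataset()].
#' @param path Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_platform_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "platform_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    plants = file.path(path, "plants.csv"),
    harvests = file.path(path, "harvests.csv"),
    evaporation = file.path(path, "evaporation.csv"),
    calibration = file.path(path, "calibration.csv"),
    meta = file.path(path, "meta.yaml")
  )
  readr::write_csv(dataset$plants, paths[["plants"]], progress = FALSE)
  readr::write_csv(dataset$harvests, paths[["harvests"]], progress = FALSE)
  readr::write_csv(dataset$evaporation, paths[["evaporation"]], progress = FALSE)
  readr::write_csv(dataset$calibration, paths[["calibration"]], progress = FALSE)
  yaml::write_yaml(
    list(treatment_onset_dae = dataset$treatment_onset_dae,
         experiment_id = dataset$experiment_id),
    paths[["meta"]]
  )
  invisible(paths)
}

#' Read a field trial network from CSV files
#'
#' @param trials_path CSV of environment-by-genotype yields with sowing,
#'   emergence and maturity dates (ISO-8601).
#' @param rainfall_path CSV of monthly rainfall per environment
#'   (`environment_id`, `month`, `rainfall_mm`).
#' @return A validated [field_dataset()].
#' @export
read_field_csv <- function(trials_path, rainfall_path) {
  for (f in c(trials_path, rainfall_path)) {
    if (!file.exists(f)) {
      abort(sprintf("file not found: %s", f), class = "phenoeff_io_error")
    }
  }
  trials <- readr::read_csv(trials_path, show_col_types = FALSE, progress = FALSE)
  rainfall <- readr::read_csv(rainfall_path, show_col_types = FALSE, progress = FALSE)
  field_dataset(trials, rainfall)
}

#' Write a field trial network to CSV files
#'
#' @param dataset A [field_dataset()].
#' @param trials_path,rainfall_path Output CSV paths.
#' @return Invisibly, the paths written.
#' @export
write_field_csv <- function(dataset, trials_path, rainfall_path) {
  stopifnot(inherits(dataset, "field_dataset"))
  readr::write_csv(dataset$trials, trials_path, progress = FALSE)
  readr::write_csv(dataset$rainfall, rainfall_path, progress = FALSE)
  invisible(c(trials = trials_path, rainfall = rainfall_path))
}

#' Write a set of result tables plus run metadata
#'
#' Writes one CSV per named table and a `run_metadata.yaml` echoing the
#' configuration, seed and package version. Given identical tables and seed,
#' the data CSVs are byte-identical across runs (the metadata timestamp is the
#' only run-varying output).
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional list echoed into the metadata file.
#' @param seed Optional seed echoed into the metadata file.
#' @return Character vector of written paths (metadata last).
#' @export
write_report <- function(tables, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    abort(sprintf("output directory not writable: %s", out_dir),
          class = "phenoeff_io_error")
  }
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(tables[[nm]]), p, progress = FALSE)
    p
  }, character(1))
  meta_path <- file.path(out_dir, "run_metadata.yaml")
  yaml::write_yaml(
    list(
      package = "phenoeff",
      version = as.character(packageVersion("phenoeff")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed,
      tables = as.list(names(tables)),
      config = config
    ),
    meta_path
  )
  c(paths, metadata = meta_path)
}
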