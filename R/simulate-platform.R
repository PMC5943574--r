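# Draw per-genotype effect vectors with an exact in-sample correlation
# structure. For a small cultivar panel the coupling parameter is
# interpreted as the realized correlation among the panel's true effects
# (cor(u, v) == rho exactly), constructed by orthogonalising standard-normal
# draws; a third vector w (e.g. intrinsic vigour) is returned exactly
# uncorrelated with both, so unrelated genotype effects cannot pick up
# chance correlations with the tolerance axis in a panel this small. Needs
# >= 4 genotypes; falls back to independent standardized draws otherwise.
.coupled_effects <- function(n, rho) {
  z <- matrix(rnorm(3 * n), n, 3)
  if (n < 4 || rho == 0) {
    s <- scale(z)
    return(list(u = s[, 1], v = s[, 2], w = s[, 3]))
  }
  basis <- matrix(0, n, 3)
  for (j in 1:3) {
    e <- z[, j] - mean(z[, j])
    if (j > 1) {
      for (k in seq_len(j - 1)) e <- e - sum(e * basis[, k]) * basis[, k]
    }
    basis[, j] <- e / sqrt(sum(e^2))
  }
  s1 <- sqrt(n - 1)
  list(
    u = basis[, 1] * s1,
    v = (rho * basis[, 1] + sqrt(1 - rho^2) * basis[, 2]) * s1,
    w = basis[, 3] * s1
  )
}

#' Configuration for a synthetic platform experiment
#'
#' Defaults emulate a seven-genotype soybean screen on an automated
#' greenhouse platform: two water regimes (well-watered throughout vs a
#' water deficit imposed at 33 DAE), harvest at 57 DAE, leaf area measured at
#' 13/20/27/33/38/44/57 DAE, exponential-phase leaf growth, transpiration
#' proportional to transpiring surface scaled per plant so transpiration
#' efficiency is a genotype property, and a built-in negative coupling
#' between genotype transpiration efficiency and drought sensitivity.
#'
#' @param n_genotypes Number of genotypes.
#' @param n_replicates Replicate plants per genotype per treatment.
#' @param treatments Named numeric vector of post-onset growth-rate
#'   multipliers per treatment (1 = well-watered; values below 1 are deficit
#'   intensities).
#' @param onset_dae,final_dae Treatment onset and harvest days (DAE).
#' @param measurement_dae Days leaf area is measured.
#' @param la0 Leaf area at emergence, cm2.
#' @param rer_mean Mean relative expansion rate, 1/d.
#' @param rer_genotype_sd,rer_plant_sd Genotype and residual (plant)
#'   standard deviations of RER, 1/d.
#' @param sens_ge_sd Genotype-by-treatment sd of the per-plant sensitivity
#'   multiplier (perturbs how strongly a given plant expresses its
#'   genotype's drought sensitivity).
#' @param la_noise_sd Log-scale measurement noise of leaf area.
#' @param te_mean,te_genotype_sd,te_plant_sd Transpiration efficiency mean
#'   and genotype / plant standard deviations, g/kg.
#' @param sens_sd Standard deviation of the per-genotype drought-sensitivity
#'   multiplier (mean 1; larger = stronger growth reduction under deficit).
#' @param coupling Realized correlation between genotype TE and sensitivity
#'   (default -0.9: efficient genotypes tolerate drought).
#' @param transp_noise_sd Multiplicative day-to-day (biological) noise of
#'   true transpiration.
#' @param weighing_noise_sd Standard deviation of each pot-weight reading, g
#'   (load cell + handling). Reading errors dominate single-day balances but
#'   telescope out of cumulative transpiration, as on a real platform.
#' @param la_offset Baseline transpiring surface of a seedling, cm2
#'   (cotyledons etc.), added to leaf area in the transpiration model.
#' @param gs_dae,leaf_temp_dae Measurement days for stomatal conductance and
#'   leaf temperature.
#' @param evap_mean,evap_sd Mean and day-to-day sd of soil evaporation, g/d.
#' @param n_evap_pots Number of plantless control pots.
#' @param pot_weight0 Initial (post-irrigation) pot weight, g.
#' @param seed Integer seed; every random draw flows from it.
#' @return A `platform_sim_config` list.
#' @export
platform_sim_config <- function(n_genotypes = 7,
                                n_replicates = 8,
                                treatments = c(WW = 1, WD = 0.79),
                                onset_dae = 33,
                                final_dae = 57,
                                measurement_dae = c(13, 20, 27, 33, 38, 44, 57),
                                la0 = 2,
                                rer_mean = 0.12,
                                rer_genotype_sd = 0.006,
                                rer_plant_sd = 0.0015,
                                sens_ge_sd = 0.05,
                                la_noise_sd = 0.08,
                                te_mean = 3.7,
                                te_genotype_sd = 0.35,
                                te_plant_sd = 0.08,
                                sens_sd = 0.35,
                                coupling = -0.9,
                                transp_noise_sd = 0.08,
                                weighing_noise_sd = 1.2,
                                la_offset = 2.5,
                                gs_dae = c(17, 24, 37, 46),
                                leaf_temp_dae = c(17, 18, 24, 37, 41, 46, 49, 53),
                                evap_mean = 12,
                                evap_sd = 2,
                                n_evap_pots = 3,
                                pot_weight0 = 5000,
                                seed = 1L) {
  stopifnot(
    n_genotypes >= 2, n_replicates >= 2,
    abs(coupling) <= 1, sens_sd >= 0,
    onset_dae > 0, onset_dae < final_dae,
    all(measurement_dae <= final_dae),
    !is.null(names(treatments)), all(treatments > 0), all(treatments <= 1)
  )
  structure(as.list(environment()), class = "platform_sim_config")
}

#' Simulate a platform experiment with known ground truth
#'
#' Generates a complete [platform_dataset()] — daily leaf area (on the
#' measurement schedule), pot weights, irrigation, evaporation controls,
#' fresh-weight calibration, harvest records, temperatures and stomatal
#' conductance — whose statistical structure matches what the analysis
#' pipeline assumes:
#'
#' * leaf area grows exponentially; the water deficit multiplies the
#'   expansion rate after onset by a treatment intensity scaled per genotype
#'   by its sensitivity multiplier (plus genotype-by-treatment noise);
#' * daily transpiration is proportional to transpiring surface, calibrated
#'   per plant so that shoot dry weight per unit cumulative water equals the
#'   plant's transpiration-efficiency value; pot weights are generated from
#'   the exact water-balance identity the recovery uses, so recovered
#'   transpiration equals the generated series;
#' * genotype TE and drought sensitivity are correlated at exactly
#'   `coupling` across the panel.
#'
#' @param config A [platform_sim_config()].
#' @return List with `data` (a [platform_dataset()]) and `truth` (list of
#'   tibbles: `genotypes` with true effects, `plants` with per-plant values,
#'   `transpiration` with the generated daily series).
#' @export
simulate_platform_experiment <- function(config = platform_sim_config()) {
  stopifnot(inherits(config, "platform_sim_config"))
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)

  genos <- sprintf("G%02d", seq_len(cf$n_genotypes))
  eff <- .coupled_effects(cf$n_genotypes, cf$coupling)
  te_g <- cf$te_mean + cf$te_genotype_sd * eff$u
  sens_g <- 1 + cf$sens_sd * eff$v # corr(te_g, sens_g) = coupling
  rer_g <- cf$rer_mean + cf$rer_genotype_sd * eff$w # vigour: tolerance-neutral
  truth_geno <- tibble::tibble(
    genotype = genos, te = te_g, sensitivity = sens_g, rer = rer_g
  )

  days <- 0:cf$final_dae
  n_days <- length(days)
  # shared daily environment: afternoon VPD and soil evaporation
  vpd_day <- runif(n_days, 1.2, 2.0)
  evap_true <- pmax(cf$evap_mean + cf$evap_sd * sin(days / 4) +
                      rnorm(n_days, 0, 0.5), 1)
  controls <- tidyr::expand_grid(
    dae = days, pot_id = sprintf("E%d", seq_len(cf$n_evap_pots))
  )
  controls$evaporation <- evap_true[match(controls$dae, days)] +
    rnorm(nrow(controls), 0, 0.3)
  evap_used <- tapply(controls$evaporation, controls$dae, mean)
  evap_used <- evap_used[as.character(days)]

  treatments <- names(cf$treatments)
  plants_meta <- tidyr::expand_grid(
    genotype = genos, treatment = treatments, replicate = seq_len(cf$n_replicates)
  ) |>
    dplyr::mutate(plant_id = sprintf("%s_%s_%02d", .data$genotype,
                                     .data$treatment, .data$replicate))
  np <- nrow(plants_meta)
  gi <- match(plants_meta$genotype, genos)
  # per-plant growth and efficiency values
  rer_pre <- rer_g[gi] + rnorm(np, 0, cf$rer_plant_sd)
  mult <- cf$treatments[plants_meta$treatment]
  post_factor <- 1 - (1 - mult) * (sens_g[gi] + rnorm(np, 0, cf$sens_ge_sd))
  post_factor <- pmax(post_factor, 0.05)
  rer_post <- rer_pre * ifelse(mult < 1, post_factor, 1)
  te_plant <- pmax(te_g[gi] + rnorm(np, 0, cf$te_plant_sd), 0.5)

  truth_plants <- plants_meta |>
    dplyr::mutate(rer_pre = rer_pre, rer_post = rer_post, te = te_plant)

  # daily true leaf area, plants x days
  t_pre <- pmin(days, cf$onset_dae)
  t_post <- pmax(days - cf$onset_dae, 0)
  log_la <- log(cf$la0) + outer(rer_pre, t_pre) + outer(rer_post, t_post)
  la_true <- exp(log_la) # np x n_days

  # transpiration: per-plant scale so that shoot dry mass per cumulative
  # water equals the plant's TE at the anchor day (the first measurement
  # day), where the trait is screened; TE at later days drifts with growth
  surf <- la_true + cf$la_offset
  vf <- vpd_day / mean(vpd_day)
  drive <- sweep(surf[, -1, drop = FALSE], 2, vf[-1], `*`) # days 1..final
  sdw_final <- estimate_sdw(la_true[, n_days], cf$final_dae)
  anchor <- min(cf$measurement_dae)
  sdw_anchor <- estimate_sdw(la_true[, anchor + 1], anchor)
  c_plant <- (1000 * sdw_anchor / te_plant) /
    rowSums(drive[, seq_len(anchor), drop = FALSE])
  transp <- drive * c_plant *
    matrix(exp(rnorm(np * (n_days - 1), 0, cf$transp_noise_sd)), nrow = np)

  # fresh-weight calibration (weekly harvests per treatment) and the daily
  # gain the estimator derives from it; the same gains enter the generated
  # weights so the balance closes exactly
  cal_days <- seq(0, cf$final_dae, by = 7)
  sdw_daily <- estimate_sdw(la_true, matrix(days, np, n_days, byrow = TRUE))
  calibration <- purrr::map_dfr(treatments, function(tr) {
    rows <- plants_meta$treatment == tr
    tibble::tibble(
      treatment = tr, dae = cal_days,
      fresh_weight = 8 * colMeans(sdw_daily[rows, cal_days + 1, drop = FALSE])
    )
  })
  gains <- calibration |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_modify(~ plant_weight_correction(.x, days = days[-1])) |>
    dplyr::ungroup()
  gain_mat <- matrix(0, np, n_days - 1)
  for (tr in treatments) {
    g <- gains$gain[gains$treatment == tr][match(days[-1], gains$dae[gains$treatment == tr])]
    gain_mat[plants_meta$treatment == tr, ] <-
      matrix(g, sum(plants_meta$treatment == tr), n_days - 1, byrow = TRUE)
  }

  # pot weights: post-irrigation weighing, irrigated back to the initial
  # weight every day => true weight constant, irrigation = day's total water
  # loss; each recorded weight carries an independent reading error
  evap_mat <- matrix(evap_used[-1], np, n_days - 1, byrow = TRUE)
  irrigation <- transp + evap_mat + gain_mat
  pot_weight <- matrix(cf$pot_weight0, np, n_days) +
    matrix(rnorm(np * n_days, 0, cf$weighing_noise_sd), np, n_days)

  # measured leaf area on the schedule, with log-normal measurement noise
  meas_idx <- match(cf$measurement_dae, days)
  la_obs <- matrix(NA_real_, np, n_days)
  la_obs[, meas_idx] <- la_true[, meas_idx] *
    exp(matrix(rnorm(np * length(meas_idx), 0, cf$la_noise_sd), np))

  # temperatures: deficit-stressed, sensitive genotypes run warmer leaves
  air_temp_day <- 26 + rnorm(n_days, 0, 1)
  lt_idx <- match(intersect(cf$leaf_temp_dae, days), days)
  leaf_temp <- matrix(NA_real_, np, n_days)
  for (j in lt_idx) {
    stressed <- (mult < 1) & (days[j] > cf$onset_dae)
    dt <- -2 + ifelse(stressed, 1.5 * sens_g[gi], 0) + rnorm(np, 0, 0.5)
    leaf_temp[, j] <- air_temp_day[j] + dt
  }
  air_temp <- matrix(NA_real_, np, n_days)
  air_temp[, lt_idx] <- matrix(air_temp_day[lt_idx], np, length(lt_idx),
                               byrow = TRUE)

  # stomatal conductance: weakly genotype-structured, noisy (low w2)
  gs_idx <- match(intersect(cf$gs_dae, days), days)
  gs <- matrix(NA_real_, np, n_days)
  for (j in gs_idx) {
    stressed <- (mult < 1) & (days[j] > cf$onset_dae)
    gs[, j] <- 400 - 30 * (sens_g[gi] - 1) - ifelse(stressed, 120 * sens_g[gi], 0) +
      rnorm(np, 0, 60)
  }

  # np x n_days matrices unroll column-major: day blocks, plants within day
  plants <- tibble::tibble(
    plant_id = rep(plants_meta$plant_id, n_days),
    genotype = rep(plants_meta$genotype, n_days),
    treatment = rep(plants_meta$treatment, n_days),
    replicate = rep(plants_meta$replicate, n_days),
    dae = rep(days, each = np),
    leaf_area = as.vector(la_obs),
    pot_weight = as.vector(pot_weight),
    irrigation_added = as.vector(cbind(0, irrigation)),
    leaf_temp = as.vector(leaf_temp),
    air_temp = as.vector(air_temp),
    gs = as.vector(gs),
    vpd = rep(vpd_day, each = np)
  )

  # harvest at the final day: partition the true shoot mass
  lmr_p <- pmin(pmax(0.55 + rnorm(np, 0, 0.02), 0.3), 0.8)
  branch_frac <- pmin(pmax(0.25 + rnorm(np, 0, 0.05), 0), 0.6)
  sdw_harvest <- sdw_final * exp(rnorm(np, 0, 0.04))
  harvests <- tibble::tibble(
    plant_id = plants_meta$plant_id,
    dae = cf$final_dae,
    leaf_dw = lmr_p * sdw_harvest,
    stem_dw = (1 - lmr_p) * sdw_harvest,
    leaf_dw_branches = branch_frac * lmr_p * sdw_harvest,
    stem_dw_branches = branch_frac * (1 - lmr_p) * sdw_harvest,
    n_nodes = pmax(round(12 + rnorm(np, 0, 1.5)), 1),
    n_branches = pmax(round(3 + rnorm(np, 0, 1)), 0)
  )

  truth_transp <- tibble::tibble(
    plant_id = rep(plants_meta$plant_id, n_days - 1),
    dae = rep(days[-1], each = np),
    transpiration = as.vector(transp)
  )

  data <- platform_dataset(
    plants = plants,
    harvests = harvests,
    evaporation = controls,
    calibration = calibration,
    treatment_onset_dae = cf$onset_dae,
    experiment_id = sprintf("sim_platform_seed%s", cf$seed %||% "NA")
  )
  list(
    data = data,
    truth = list(genotypes = truth_geno, plants = truth_plants,
                 transpiration = truth_transp, config = cf)
  )
}

#' Simulate an intraday transpiration-rate vs VPD series
#'
#' Generates (VPD, TR) pairs from a known two-segment linear truth with
#' Gaussian noise proportional to the signal, emulating sequential pot
#' weighings across the midday VPD range.
#'
#' @param i1,s1,i2,s2,bp True segment intercepts (mg m-2 s-1), slopes
#'   (mg m-2 s-1 kPa-1) and breakpoint (kPa).
#' @param n Number of points (>= 8).
#' @param vpd_range VPD sampling range, kPa.
#' @param noise_sd Noise standard deviation as a fraction of the local
#'   signal (0 = noise-free).
#' @param seed Optional integer seed.
#' @return Tibble with `vpd` and `tr`.
#' @export
simulate_vpd_series <- function(i1 = 0, s1 = 20, i2 = 30, s2 = 8, bp = 2.5,
                                n = 30, vpd_range = c(1.2, 2.98),
                                noise_sd = 0.05, seed = NULL) {
  stopifnot(n >= 8)
  if (!is.null(seed)) set.seed(seed)
  vpd <- runif(n, vpd_range[1], vpd_range[2])
  mu <- ifelse(vpd < bp, i1 + s1 * vpd, i2 + s2 * vpd)
  tr <- mu + if (noise_sd > 0) rnorm(n, 0, noise_sd * abs(mu)) else 0
  tibble::tibble(vpd = vpd, tr = tr)
}
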