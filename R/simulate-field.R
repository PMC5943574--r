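#' Configuration for a synthetic field trial network
#'
#' Defaults emulate a national variety-trial network: 80 location-by-year
#' environments with seasonal water inputs spanning 300-1200 mm, environment
#' mean yields lying on or below a saturating envelope of water input (a
#' small fraction sits marginally above it, as real boundary data do), a
#' configurable number of environments limited by non-water factors (well
#' below the envelope band), and per-genotype sensitivity slopes of yield
#' deviation vs water input coupled to a genotype trait value
#' (transpiration efficiency).
#'
#' @param n_environments Number of environments (>= 10; default 80).
#' @param n_genotypes Number of genotypes grown in every environment.
#' @param a,b,c True envelope parameters: attainable yield (kg/ha), initial
#'   factor-use efficiency (1/mm, negative), minimum water input (mm).
#' @param water_range Range of seasonal water inputs, mm.
#' @param n_above Environments placed marginally above the envelope
#'   (default 5% of the network).
#' @param n_other_limited Environments limited by non-water factors
#'   (shortfall beyond the water-limited band; default 12.5% of the
#'   network, i.e. 10 of 80).
#' @param shortfall_frac_range Relative shortfall below the envelope for
#'   water-limited environments.
#' @param other_shortfall_frac_range Relative shortfall for the non-water
#'   limited environments (beyond the band).
#' @param slope_range Range of per-genotype yield-deviation slopes,
#'   kg/ha/mm.
#' @param te_mean,te_spread Mean and total spread (max - min) of the
#'   genotype trait values coupled to the slopes, g/kg.
#' @param te_noise_sd Noise sd of the measured per-genotype trait, g/kg.
#' @param coupling Realized correlation between genotype trait and
#'   (negated) sensitivity slope (default -0.9).
#' @param yield_noise_sd Residual sd of genotype yields within an
#'   environment, kg/ha.
#' @param crit_frac_range Critical-period rainfall as a fraction of total
#'   water input.
#' @param seed Integer seed.
#' @return A `field_sim_config` list.
#' @export
field_sim_config <- function(n_environments = 80,
                             n_genotypes = 7,
                             a = 5500, b = -0.004, c = 150,
                             water_range = c(300, 1200),
                             n_above = round(0.05 * n_environments),
                             n_other_limited = round(0.125 * n_environments),
                             shortfall_frac_range = c(0, 0.15),
                             other_shortfall_frac_range = c(0.25, 0.45),
                             slope_range = c(-5, 3),
                             te_mean = 3.7, te_spread = 0.5,
                             te_noise_sd = 0.1,
                             coupling = -0.9,
                             yield_noise_sd = 120,
                             crit_frac_range = c(0.15, 0.45),
                             seed = 1L) {
  stopifnot(n_environments >= 10, b < 0, n_genotypes >= 3,
            n_above + n_other_limited < n_environments, abs(coupling) <= 1)
  structure(as.list(environment()), class = "field_sim_config")
}

#' Simulate a field trial network with known ground truth
#'
#' Generates a [field_dataset()] (per-environment genotype yields with
#' sowing/emergence/maturity dates, and monthly rainfall series) plus the
#' ground truth needed to verify every downstream stage. Monthly rainfall is
#' constructed so that the pro-rated window sums reproduce each
#' environment's water input and critical-period rainfall exactly.
#'
#' @param config A [field_sim_config()].
#' @return List with `data` (a [field_dataset()]) and `truth` (list:
#'   `environments` tibble with water input, shortfall class and envelope
#'   values; `genotypes` tibble with true slopes and trait values;
#'   `envelope` the true parameters).
#' @export
simulate_field_network <- function(config = field_sim_config()) {
  stopifnot(inherits(config, "field_sim_config"))
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)

  ne <- cf$n_environments
  env_ids <- sprintf("E%03d", seq_len(ne))
  water <- runif(ne, cf$water_range[1], cf$water_range[2])
  env_yield <- .envelope_predict(cf$a, cf$b, cf$c, water)

  status <- rep("water_limited", ne)
  special <- sample(ne, cf$n_above + cf$n_other_limited)
  status[special[seq_len(cf$n_above)]] <- "above"
  if (cf$n_other_limited > 0) {
    status[special[cf$n_above + seq_len(cf$n_other_limited)]] <- "other_limited"
  }
  shortfall_frac <- runif(ne, cf$shortfall_frac_range[1],
                          cf$shortfall_frac_range[2])
  shortfall_frac[status == "above"] <- -runif(cf$n_above, 0.005, 0.03)
  shortfall_frac[status == "other_limited"] <-
    runif(cf$n_other_limited, cf$other_shortfall_frac_range[1],
          cf$other_shortfall_frac_range[2])
  mean_yield <- env_yield * (1 - shortfall_frac)

  # genotype sensitivity slopes coupled to the platform trait (TE): the
  # trait's spread is fixed and the realized correlation equals `coupling`
  genos <- sprintf("F%02d", seq_len(cf$n_genotypes))
  eff <- .coupled_effects(cf$n_genotypes, cf$coupling)
  te_sd <- cf$te_spread / (max(eff$u) - min(eff$u))
  te_g <- cf$te_mean + te_sd * eff$u
  slope_mid <- mean(cf$slope_range)
  slope_sd <- diff(cf$slope_range) / (max(eff$v) - min(eff$v))
  slope_g <- slope_mid + slope_sd * eff$v # corr(te, slope) = coupling
  slope_g <- slope_g - mean(slope_g) + slope_mid

  water_ref <- mean(water)
  yields <- tidyr::expand_grid(environment_id = env_ids, genotype = genos) |>
    dplyr::mutate(
      water = water[match(.data$environment_id, env_ids)],
      env_mean = mean_yield[match(.data$environment_id, env_ids)],
      yield = pmax(
        .data$env_mean + slope_g[match(.data$genotype, genos)] *
          (.data$water - water_ref) + rnorm(dplyr::n(), 0, cf$yield_noise_sd),
        100
      )
    )
  # recentre so each environment's mean matches the constructed mean yield
  yields <- yields |>
    dplyr::group_by(.data$environment_id) |>
    dplyr::mutate(yield = .data$yield - mean(.data$yield) + .data$env_mean) |>
    dplyr::ungroup()

  # calendar: southern-hemisphere summer crop; dates staggered across envs
  sowing <- as.Date("2013-11-01") + sample(0:40, ne, replace = TRUE)
  emergence <- sowing + sample(7:12, ne, replace = TRUE)
  maturity <- sowing + sample(130:160, ne, replace = TRUE)
  crit_target <- water * runif(ne, cf$crit_frac_range[1], cf$crit_frac_range[2])

  rainfall <- purrr::map_dfr(seq_len(ne), function(i) {
    .build_rainfall(env_ids[i], sowing[i], maturity[i],
                    total = water[i], critical = crit_target[i])
  })

  trials <- yields |>
    dplyr::mutate(
      sowing_date = sowing[match(.data$environment_id, env_ids)],
      emergence_date = emergence[match(.data$environment_id, env_ids)],
      maturity_date = maturity[match(.data$environment_id, env_ids)]
    ) |>
    dplyr::select("environment_id", "genotype", "yield", "sowing_date",
                  "emergence_date", "maturity_date")

  truth_env <- tibble::tibble(
    environment_id = env_ids, water_input = water,
    critical_rainfall = crit_target,
    envelope_yield = env_yield, mean_yield = mean_yield,
    shortfall_frac = shortfall_frac, status = status
  )
  truth_geno <- tibble::tibble(genotype = genos, te = te_g,
                               slope = slope_g,
                               te_measured = te_g + rnorm(cf$n_genotypes, 0,
                                                          cf$te_noise_sd))

  list(
    data = field_dataset(trials, rainfall),
    truth = list(environments = truth_env, genotypes = truth_geno,
                 envelope = c(a = cf$a, b = cf$b, c = cf$c), config = cf)
  )
}

# Build a monthly rainfall series whose pro-rated sums over the water-input
# window [sowing - 60 d, maturity] and the critical window
# [maturity - 3 months, maturity - 1 month] equal `total` and `critical`.
.build_rainfall <- function(env_id, sowing, maturity, total, critical) {
  w_start <- sowing - 60
  w_end <- maturity
  c_start <- lubridate::add_with_rollback(maturity, -months(3))
  c_end <- lubridate::add_with_rollback(maturity, -months(1))
  months_seq <- seq(lubridate::floor_date(w_start, "month"),
                    lubridate::floor_date(w_end, "month"), by = "month")
  m_start <- months_seq
  m_end <- lubridate::ceiling_date(months_seq, "month") - 1
  m_days <- as.numeric(m_end - m_start) + 1
  frac_w <- pmax(as.numeric(pmin(m_end, w_end) - pmax(m_start, w_start)) + 1, 0) / m_days
  frac_c <- pmax(as.numeric(pmin(m_end, c_end) - pmax(m_start, c_start)) + 1, 0) / m_days

  rain <- numeric(length(months_seq))
  crit_months <- frac_c > 0
  rho <- critical / sum(frac_c[crit_months])
  rain[crit_months] <- rho
  contrib <- sum(frac_w[crit_months] * rho)
  rest <- !crit_months & frac_w > 0
  remaining <- total - contrib
  if (remaining < 0) {
    # critical target too large for the total: scale it down proportionally
    rain[crit_months] <- rain[crit_months] * total / contrib
    remaining <- 0
  }
  if (any(rest) && remaining > 0) {
    u <- runif(sum(rest), 0.5, 1.5)
    rain[rest] <- remaining * u / sum(frac_w[rest] * u)
  }
  tibble::tibble(environment_id = env_id, month = months_seq,
                 rainfall_mm = rain)
}
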