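#' Drought susceptibility index
#'
#' DSI of a genotype for a trait measured under well-watered (ww) and
#' water-deficit (wd) regimes:
#' `DSI = (1 - y_wd / y_ww) / (1 - x_wd / x_ww)`,
#' where `y` are the genotype's means and `x` the population means (unweighted
#' means of genotype means). DSI = 1 marks average susceptibility, 0 an
#' unaffected genotype, negative values a trait that increases under deficit.
#' Undefined when the population is unaffected (`x_wd = x_ww`).
#'
#' @param y_ww,y_wd Genotype trait means under the two regimes (`y_ww > 0`).
#' @param x_ww,x_wd Population trait means under the two regimes.
#' @return DSI (vectorised over genotypes).
#' @export
#' @examples
#' dsi(y_ww = 10, y_wd = 6, x_ww = 10, x_wd = 8) # 2
dsi <- function(y_ww, y_wd, x_ww, x_wd) {
  if (any(y_ww <= 0, na.rm = TRUE) || any(x_ww <= 0, na.rm = TRUE)) {
    abort("well-watered means must be positive", class = "phenoeff_domain_error")
  }
  denom <- 1 - x_wd / x_ww
  if (any(denom == 0, na.rm = TRUE)) {
    warn("population unaffected by the deficit (x_wd = x_ww): DSI undefined")
  }
  out <- (1 - y_wd / y_ww) / denom
  out[rep_len(denom == 0, length(out))] <- NA_real_
  out
}

#' Per-genotype DSI table for one trait at one time
#'
#' Computes genotype means per water regime from replicate-level trait
#' observations, population means as unweighted means of genotype means, and
#' the DSI per genotype. Genotypes missing either regime are excluded from the
#' table and from the population means, with a diagnostic attribute.
#'
#' @param obs Trait observations: tibble with `trait`, `dae`, `treatment`,
#'   `genotype`, `replicate`, `value`.
#' @param trait Trait label to select.
#' @param dae Measurement day to select.
#' @param ww_label,wd_label Treatment labels for the well-watered and
#'   water-deficit regimes.
#' @return Tibble with one row per genotype: `genotype`, `trait`, `dae`,
#'   `y_ww`, `y_wd`, `x_ww`, `x_wd`, `dsi`. Excluded genotypes are listed in
#'   the `excluded` attribute.
#' @export
dsi_table <- function(obs, trait, dae, ww_label = "WW", wd_label = "WD") {
  sel <- obs |>
    dplyr::filter(.data$trait == !!trait, .data$dae == !!dae,
                  .data$treatment %in% c(ww_label, wd_label),
                  is.finite(.data$value))
  means <- sel |>
    dplyr::group_by(.data$genotype, .data$treatment) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "value")
  for (lbl in c(ww_label, wd_label)) {
    if (!lbl %in% names(means)) means[[lbl]] <- NA_real_
  }
  complete <- !is.na(means[[ww_label]]) & !is.na(means[[wd_label]])
  excluded <- means$genotype[!complete]
  means <- means[complete, , drop = FALSE]
  if (nrow(means) == 0) {
    out <- tibble::tibble(genotype = character(), trait = character(),
                          dae = integer(), y_ww = double(), y_wd = double(),
                          x_ww = double(), x_wd = double(), dsi = double())
    attr(out, "excluded") <- excluded
    return(out)
  }
  x_ww <- mean(means[[ww_label]])
  x_wd <- mean(means[[wd_label]])
  out <- tibble::tibble(
    genotype = means$genotype,
    trait = trait,
    dae = as.integer(dae),
    y_ww = means[[ww_label]],
    y_wd = means[[wd_label]],
    x_ww = x_ww,
    x_wd = x_wd,
    dsi = dsi(means[[ww_label]], means[[wd_label]], x_ww, x_wd)
  )
  attr(out, "excluded") <- excluded
  out
}

#' Variance components of a random-effects genotype model
#'
#' Estimates genotypic, residual and (for multi-environment layouts)
#' genotype-by-environment variance components. Balanced layouts use the
#' closed-form ANOVA expected-mean-squares estimators — one-way:
#' `sigma2_e = MSE`, `sigma2_g = (MSG - MSE) / r`; two-way random:
#' `sigma2_e = MSE`, `sigma2_ge = (MSGE - MSE) / r`,
#' `sigma2_g = (MSG - MSGE) / (r * t)` — which coincide with REML there.
#' Unbalanced layouts are estimated by restricted maximum likelihood of the
#' same random-effects model via [lme4::lmer()]. Negative closed-form
#' estimates are truncated to zero and flagged.
#'
#' @param obs Tibble with `genotype`, `value`, and (for `model = "two_way"`)
#'   `environment` columns; one row per replicate observation.
#' @param model `"one_way"` (genotypes x replicates) or `"two_way"`
#'   (genotypes x environments x replicates, environment fixed).
#' @return Tibble with `sigma2_g`, `sigma2_e`, `sigma2_ge` (NA for one-way),
#'   `r` (replicates per cell), `t` (number of environments; 1 for one-way),
#'   `truncated` (logical), `method` ("ems" or "reml").
#' @export
variance_components <- function(obs, model = c("one_way", "two_way")) {
  model <- match.arg(model)
  obs <- dplyr::filter(tibble::as_tibble(obs), is.finite(.data$value))
  .assert_cols(obs, c("genotype", "value"), "observations")
  if (dplyr::n_distinct(obs$genotype) < 2) {
    abort("need at least 2 genotypes", class = "phenoeff_estimation_error")
  }

  if (model == "one_way") {
    counts <- dplyr::count(obs, .data$genotype)
    if (any(counts$n < 2)) {
      abort("need at least 2 replicates per genotype",
            class = "phenoeff_estimation_error")
    }
    balanced <- dplyr::n_distinct(counts$n) == 1
    if (balanced) {
      r <- counts$n[1]
      g <- nrow(counts)
      gm <- mean(obs$value)
      means <- obs |>
        dplyr::group_by(.data$genotype) |>
        dplyr::summarise(m = mean(.data$value), .groups = "drop")
      msg <- r * sum((means$m - gm)^2) / (g - 1)
      mse_num <- obs |>
        dplyr::left_join(means, by = "genotype") |>
        dplyr::summarise(ss = sum((.data$value - .data$m)^2)) |>
        dplyr::pull(.data$ss)
      mse <- mse_num / (g * (r - 1))
      s2g_raw <- (msg - mse) / r
      truncated <- s2g_raw < 0
      return(tibble::tibble(
        sigma2_g = max(s2g_raw, 0), sigma2_e = mse, sigma2_ge = NA_real_,
        r = r, t = 1L, truncated = truncated, method = "ems"
      ))
    }
    fit <- lme4::lmer(value ~ (1 | genotype), data = obs, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2g <- vc$vcov[vc$grp == "genotype"]
    s2e <- vc$vcov[vc$grp == "Residual"]
    return(tibble::tibble(
      sigma2_g = s2g, sigma2_e = s2e, sigma2_ge = NA_real_,
      r = round(mean(counts$n)), t = 1L, truncated = FALSE, method = "reml"
    ))
  }

  .assert_cols(obs, "environment", "two-way observations")
  t_env <- dplyr::n_distinct(obs$environment)
  if (t_env < 2) {
    abort("two-way model needs at least 2 environments",
          class = "phenoeff_estimation_error")
  }
  cells <- dplyr::count(obs, .data$genotype, .data$environment)
  g <- dplyr::n_distinct(obs$genotype)
  balanced <- nrow(cells) == g * t_env && dplyr::n_distinct(cells$n) == 1 &&
    cells$n[1] >= 2
  if (balanced) {
    r <- cells$n[1]
    gm <- mean(obs$value)
    gmeans <- obs |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(m = mean(.data$value), .groups = "drop")
    emeans <- obs |>
      dplyr::group_by(.data$environment) |>
      dplyr::summarise(m = mean(.data$value), .groups = "drop")
    cmeans <- obs |>
      dplyr::group_by(.data$genotype, .data$environment) |>
      dplyr::summarise(m = mean(.data$value), .groups = "drop")
    msg <- r * t_env * sum((gmeans$m - gm)^2) / (g - 1)
    inter <- cmeans |>
      dplyr::left_join(dplyr::rename(gmeans, gm_g = "m"), by = "genotype") |>
      dplyr::left_join(dplyr::rename(emeans, gm_e = "m"), by = "environment")
    ss_ge <- sum((inter$m - inter$gm_g - inter$gm_e + gm)^2)
    msge <- r * ss_ge / ((g - 1) * (t_env - 1))
    mse_num <- obs |>
      dplyr::left_join(dplyr::rename(cmeans, cm = "m"),
                       by = c("genotype", "environment")) |>
      dplyr::summarise(ss = sum((.data$value - .data$cm)^2)) |>
      dplyr::pull(.data$ss)
    mse <- mse_num / (g * t_env * (r - 1))
    s2ge_raw <- (msge - mse) / r
    s2g_raw <- (msg - msge) / (r * t_env)
    truncated <- s2ge_raw < 0 || s2g_raw < 0
    return(tibble::tibble(
      sigma2_g = max(s2g_raw, 0), sigma2_e = mse,
      sigma2_ge = max(s2ge_raw, 0),
      r = r, t = as.integer(t_env), truncated = truncated, method = "ems"
    ))
  }
  fit <- lme4::lmer(
    value ~ environment + (1 | genotype) + (1 | genotype:environment),
    data = obs, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2g <- vc$vcov[vc$grp == "genotype"]
  s2ge <- vc$vcov[vc$grp == "genotype:environment"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  tibble::tibble(
    sigma2_g = s2g, sigma2_e = s2e, sigma2_ge = s2ge,
    r = round(mean(cells$n)), t = as.integer(t_env),
    truncated = FALSE, method = "reml"
  )
}

#' Repeatability from variance components
#'
#' Fraction of the variance of genotype means attributable to genotypic
#' variance — the broad-sense statistic suited to cultivar panels of diverse
#' pedigree. Before the onset of a water treatment (a single environment):
#' `w2 = sigma2_g / (sigma2_g + sigma2_e / r)`. After onset, with `t`
#' soil-water environments:
#' `w2 = sigma2_g / (sigma2_g + sigma2_e / (r * t) + sigma2_ge / t)`.
#'
#' @param components One-row tibble from [variance_components()] (or a list
#'   with the same fields).
#' @param scope `"single_env"` or `"multi_env"`.
#' @param r,t Override the replicate count / environment count stored in
#'   `components` (e.g. when the repeatability target design differs from the
#'   estimation design).
#' @return Repeatability in `[0, 1]`; `NA` with a warning when all components
#'   are zero.
#' @export
repeatability <- function(components, scope = c("single_env", "multi_env"),
                          r = NULL, t = NULL) {
  scope <- match.arg(scope)
  s2g <- components$sigma2_g
  s2e <- components$sigma2_e
  r <- r %||% components$r
  if (scope == "single_env") {
    denom <- s2g + s2e / r
  } else {
    s2ge <- components$sigma2_ge
    t <- t %||% components$t
    if (is.null(t) || is.na(t) || is.null(s2ge) || is.na(s2ge)) {
      abort("multi_env repeatability needs sigma2_ge and t",
            class = "phenoeff_domain_error")
    }
    denom <- s2g + s2e / (r * t) + s2ge / t
  }
  if (isTRUE(denom == 0)) {
    warn("all variance components are zero: repeatability undefined")
    return(NA_real_)
  }
  s2g / denom
}
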