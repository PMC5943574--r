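#' Regression of a candidate trait on the target trait
#'
#' Ordinary least-squares simple regression of per-genotype candidate-trait
#' means on the per-genotype target values (typically the drought
#' susceptibility index for final shoot dry weight), with the two-sided
#' p-value for the slope. This is criterion 1 of the selection framework, and
#' its determination coefficient feeds criterion 2.
#'
#' @param trait_values Named numeric vector or tibble (`genotype`, `value`)
#'   of per-genotype candidate-trait means.
#' @param target Named numeric vector or tibble (`genotype`, `target`) of the
#'   per-genotype target values.
#' @return One-row tibble: `r2`, `p_value`, `slope`, `intercept`, `n`.
#' @export
trait_vs_target_regression <- function(trait_values, target) {
  as_named <- function(x, value_col) {
    if (is.data.frame(x)) setNames(x[[value_col]], x$genotype) else x
  }
  tv <- as_named(trait_values, "value")
  tg <- as_named(target, if (is.data.frame(target) && "target" %in% names(target))
    "target" else "value")
  shared <- intersect(names(tv), names(tg))
  if (length(shared) >= 3) {
    tv <- tv[shared]
    tg <- tg[shared]
  }
  .ols_inference(x = as.numeric(tg), y = as.numeric(tv))
}

#' Phenotyping cost in plant-days
#'
#' Time-and-space cost proxy for measuring a trait on a platform: the number
#' of replicate plants occupied times the days of platform occupancy until
#' the measurement.
#'
#' @param n_replicates Number of replicate plants (>= 1).
#' @param dae Measurement day, days after emergence (> 0).
#' @return Cost in plant-days (vectorised).
#' @export
phenotyping_cost <- function(n_replicates, dae) {
  if (any(n_replicates < 1, na.rm = TRUE) || any(dae <= 0, na.rm = TRUE)) {
    abort("need n_replicates >= 1 and dae > 0", class = "phenoeff_domain_error")
  }
  n_replicates * dae
}

#' Determination-to-relative-cost ratio
#'
#' Criterion 2 of the framework: the determination coefficient of the
#' trait-vs-target regression divided by the relative phenotyping cost (trait
#' cost over target-trait cost). An indirect trait is worth adopting when the
#' ratio is large; the default screen keeps ratios of at least 2.
#'
#' @param r2 Determination coefficient.
#' @param cost_trait,cost_target Phenotyping costs in plant-days (> 0).
#' @return Dimensionless efficiency ratio (vectorised).
#' @export
efficiency_ratio <- function(r2, cost_trait, cost_target) {
  if (any(cost_trait <= 0, na.rm = TRUE) || any(cost_target <= 0, na.rm = TRUE)) {
    abort("costs must be positive", class = "phenoeff_domain_error")
  }
  r2 / (cost_trait / cost_target)
}

#' Repeatability per trait and measurement day
#'
#' Computes the repeatability of every trait-by-day combination in a trait
#' observation table. Before the water-treatment onset all plants share one
#' environment, so the single-environment form applies with all plants as
#' replicates; from onset onward the soil-water treatments are environments
#' and the multi-environment form applies (genotype-by-environment variance
#' included). Components come from the balanced expected-mean-squares
#' estimators with `r` taken as the average cell count.
#'
#' @param obs Trait observation table (see [platform_traits()]).
#' @param onset_dae Day the water treatment was imposed.
#' @return Tibble with `trait`, `dae`, `scope`, `w2`, `sigma2_g`, `sigma2_e`,
#'   `sigma2_ge`, `r`, `t`.
#' @export
repeatability_table <- function(obs, onset_dae) {
  obs <- dplyr::filter(obs, is.finite(.data$value))
  combos <- dplyr::distinct(obs, .data$trait, .data$dae)
  purrr::pmap_dfr(combos, function(trait, dae) {
    sel <- obs[obs$trait == trait & obs$dae == dae, , drop = FALSE]
    multi <- !is.na(onset_dae) && dae > onset_dae &&
      dplyr::n_distinct(sel$treatment) >= 2
    vc <- tryCatch({
      if (multi) {
        variance_components(
          dplyr::rename(sel, environment = "treatment"), model = "two_way"
        )
      } else {
        variance_components(sel, model = "one_way")
      }
    }, error = function(e) NULL)
    if (is.null(vc)) {
      return(tibble::tibble(
        trait = trait, dae = dae, scope = NA_character_, w2 = NA_real_,
        sigma2_g = NA_real_, sigma2_e = NA_real_, sigma2_ge = NA_real_,
        r = NA_integer_, t = NA_integer_
      ))
    }
    scope <- if (multi) "multi_env" else "single_env"
    tibble::tibble(
      trait = trait, dae = dae, scope = scope,
      w2 = repeatability(vc, scope = scope),
      sigma2_g = vc$sigma2_g, sigma2_e = vc$sigma2_e,
      sigma2_ge = vc$sigma2_ge, r = vc$r, t = vc$t
    )
  })
}

# Fast EMS-based components per (trait, dae, [treatment]) group, for the
# audit table. Balanced designs assumed; r is the average cell count.
.w2_fast <- function(obs, onset_dae) {
  pre <- dplyr::filter(obs, is.na(onset_dae) | .data$dae <= onset_dae)
  post <- dplyr::filter(obs, !is.na(onset_dae) & .data$dae > onset_dae)

  one_way <- function(df) {
    df |>
      dplyr::group_by(.data$trait, .data$dae, .data$genotype) |>
      dplyr::summarise(m = mean(.data$value),
                       ss = sum((.data$value - mean(.data$value))^2),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::group_by(.data$trait, .data$dae) |>
      dplyr::summarise(
        g = dplyr::n(), r = mean(.data$n),
        msg = sum(.data$n * (.data$m - sum(.data$n * .data$m) / sum(.data$n))^2) /
          (dplyr::n() - 1),
        mse = sum(.data$ss) / pmax(sum(.data$n) - dplyr::n(), 1),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        sigma2_e = .data$mse,
        sigma2_g = pmax((.data$msg - .data$mse) / .data$r, 0),
        w2 = ifelse(.data$sigma2_g + .data$sigma2_e == 0, NA_real_,
                    .data$sigma2_g / (.data$sigma2_g + .data$sigma2_e / .data$r)),
        scope = "single_env"
      ) |>
      dplyr::select("trait", "dae", "scope", "w2", "sigma2_g", "sigma2_e")
  }

  two_way <- function(df) {
    cells <- df |>
      dplyr::group_by(.data$trait, .data$dae, .data$genotype, .data$treatment) |>
      dplyr::summarise(cm = mean(.data$value),
                       ss = sum((.data$value - mean(.data$value))^2),
                       n = dplyr::n(), .groups = "drop")
    cells |>
      dplyr::group_by(.data$trait, .data$dae) |>
      dplyr::group_modify(function(x, key) {
        g <- dplyr::n_distinct(x$genotype)
        t_env <- dplyr::n_distinct(x$treatment)
        if (g < 2 || t_env < 2) {
          return(tibble::tibble(scope = NA_character_, w2 = NA_real_,
                                sigma2_g = NA_real_, sigma2_e = NA_real_))
        }
        r <- mean(x$n)
        gm <- mean(x$cm)
        gmean <- tapply(x$cm, x$genotype, mean)
        emean <- tapply(x$cm, x$treatment, mean)
        msg <- r * t_env * sum((gmean - gm)^2) / (g - 1)
        resid <- x$cm - gmean[x$genotype] - emean[x$treatment] + gm
        msge <- r * sum(resid^2) / ((g - 1) * (t_env - 1))
        mse <- sum(x$ss) / max(sum(x$n) - g * t_env, 1)
        s2ge <- max((msge - mse) / r, 0)
        s2g <- max((msg - msge) / (r * t_env), 0)
        denom <- s2g + mse / (r * t_env) + s2ge / t_env
        tibble::tibble(scope = "multi_env",
                       w2 = ifelse(denom == 0, NA_real_, s2g / denom),
                       sigma2_g = s2g, sigma2_e = mse)
      }) |>
      dplyr::ungroup()
  }

  dplyr::bind_rows(
    if (nrow(pre) > 0) one_way(pre),
    if (nrow(post) > 0) two_way(post)
  )
}

#' Score every trait-by-day-by-treatment combination
#'
#' Builds the full audit table of the four-criterion framework: for every
#' (trait, dae, treatment) combination in the observation table, the
#' regression of its genotype means on the target values (`r2`, `p_value`,
#' `slope`), the phenotyping cost and cost ratio, and the repeatability of
#' the trait at that day. Every combination appears exactly once; nothing is
#' silently dropped (combinations that cannot be scored carry `NA`s).
#'
#' @param obs Trait observation table (see [platform_traits()]).
#' @param target Tibble (`genotype`, `target`) of per-genotype target values,
#'   e.g. the `dsi` column of [dsi_table()] renamed to `target`.
#' @param onset_dae Water-treatment onset day (for the repeatability scope).
#' @param target_cost Phenotyping cost of the target trait in plant-days. The
#'   default charges one replicate set at the target measurement day, taken
#'   as the latest day in `obs`.
#' @param exclude Optional tibble (`trait`, `dae`) of combinations to drop
#'   from scoring (typically the target trait itself).
#' @param score_dae Optional integer vector restricting scoring to a
#'   measurement schedule: only observations at these days enter the audit
#'   table. `NULL` (default) scores every day present.
#' @return Tibble with one row per combination: `trait`, `dae`, `treatment`,
#'   `n_genotypes`, `n_replicates`, `r2`, `p_value`, `slope`, `cost`,
#'   `relative_cost`, `ratio`, `w2`.
#' @export
efficiency_table <- function(obs, target, onset_dae = NA,
                             target_cost = NULL, exclude = NULL,
                             score_dae = NULL) {
  obs <- dplyr::filter(obs, is.finite(.data$value))
  stopifnot(all(c("genotype", "target") %in% names(target)))
  if (!is.null(score_dae)) {
    obs <- dplyr::filter(obs, .data$dae %in% score_dae)
  }
  if (!is.null(exclude)) {
    obs <- dplyr::anti_join(obs, exclude, by = c("trait", "dae"))
  }
  if (is.null(target_cost)) {
    reps_final <- obs |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(r = dplyr::n_distinct(.data$replicate), .groups = "drop")
    target_cost <- round(mean(reps_final$r)) * max(obs$dae)
  }

  gmeans <- obs |>
    dplyr::group_by(.data$trait, .data$dae, .data$treatment, .data$genotype) |>
    dplyr::summarise(value = mean(.data$value),
                     n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::inner_join(target, by = "genotype")

  reg <- gmeans |>
    dplyr::group_by(.data$trait, .data$dae, .data$treatment) |>
    dplyr::summarise(
      n_genotypes = dplyr::n(),
      n_replicates = round(mean(.data$n_rep)),
      fit = list(.ols_inference(.data$target, .data$value)),
      .groups = "drop"
    ) |>
    tidyr::unnest("fit") |>
    dplyr::select(-"intercept", -"n")

  w2 <- .w2_fast(obs, onset_dae)

  reg |>
    dplyr::mutate(
      cost = phenotyping_cost(.data$n_replicates, .data$dae),
      relative_cost = .data$cost / target_cost,
      ratio = .data$r2 / .data$relative_cost
    ) |>
    dplyr::left_join(w2[, c("trait", "dae", "w2")], by = c("trait", "dae")) |>
    dplyr::arrange(.data$trait, .data$dae, .data$treatment)
}

#' Selection thresholds for the four-criterion framework
#'
#' @param alpha Significance level for the trait-vs-target regression
#'   (criterion 1; default 0.05).
#' @param ratio_min Minimum determination-to-relative-cost ratio
#'   (criterion 2; default 2).
#' @param w2_min Minimum repeatability (criterion 4; default 0.5).
#' @param max_dae Optional hard ceiling on measurement day (e.g. the
#'   treatment onset, to demand traits measurable before stress); `Inf`
#'   leaves earliness as an ordering preference only.
#' @return A `selection_config` list.
#' @export
selection_config <- function(alpha = 0.05, ratio_min = 2, w2_min = 0.5,
                             max_dae = Inf) {
  stopifnot(alpha > 0, alpha < 1, ratio_min > 0, w2_min >= 0, w2_min <= 1)
  structure(list(alpha = alpha, ratio_min = ratio_min, w2_min = w2_min,
                 max_dae = max_dae),
            class = "selection_config")
}

#' Apply the four selection criteria and rank the survivors
#'
#' Sequentially screens the audit table: (1) keep significant regressions
#' (`p_value <= alpha`); (2) keep efficient traits (`ratio >= ratio_min`);
#' (3) order by earliness (ascending measurement day; optionally a hard
#' ceiling); (4) keep repeatable traits (`w2 >= w2_min`). The criteria are
#' pure predicates, so the surviving set does not depend on evaluation order;
#' the final ranking among survivors is lexicographic: earliest day, then
#' highest repeatability, then highest efficiency ratio. The full audit table
#' is returned with per-criterion flags; no row is dropped.
#'
#' @param rows Audit table from [efficiency_table()].
#' @param config A [selection_config()].
#' @return `rows` with added logical columns `pass_significance`,
#'   `pass_ratio`, `pass_earliness`, `pass_w2`, `selected` (all four), and
#'   integer `rank` (NA for non-selected rows).
#' @export
select_traits <- function(rows, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  out <- rows |>
    dplyr::mutate(
      pass_significance = !is.na(.data$p_value) & .data$p_value <= config$alpha,
      pass_ratio = !is.na(.data$ratio) & .data$ratio >= config$ratio_min,
      pass_earliness = .data$dae <= config$max_dae,
      pass_w2 = !is.na(.data$w2) & .data$w2 >= config$w2_min,
      selected = .data$pass_significance & .data$pass_ratio &
        .data$pass_earliness & .data$pass_w2
    )
  ord <- order(out$dae, -out$w2, -out$ratio)
  rank <- rep(NA_integer_, nrow(out))
  sel_in_order <- ord[out$selected[ord]]
  rank[sel_in_order] <- seq_along(sel_in_order)
  out$rank <- rank
  dplyr::arrange(out, is.na(.data$rank), .data$rank, .data$dae)
}
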