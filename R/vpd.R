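#' Two-segment linear fit of transpiration rate vs VPD
#'
#' Fits the piecewise-linear response of transpiration rate (TR, mg m^-2
#' s^-1) to vapour pressure deficit (VPD, kPa):
#' TR = I1 + S1 * VPD below the breakpoint, TR = I2 + S2 * VPD at or above it.
#' Both intercepts are free parameters (no continuity constraint at the
#' breakpoint), matching the four-parameter reporting convention; a
#' continuity-constrained variant is available for sensitivity checks.
#'
#' When `bp_fixed` is supplied, each side is fit by ordinary least squares
#' independently. Otherwise the breakpoint is chosen by grid search at
#' `bp_grid` resolution over the observed VPD range, keeping only candidates
#' leaving at least two points with distinct VPD on each side, and minimising
#' the total residual sum of squares; ties break toward the smaller
#' breakpoint.
#'
#' @param data Data frame with the TR and VPD columns.
#' @param tr,vpd Column names (tidy-eval) holding transpiration rate and VPD.
#' @param bp_fixed Optional fixed breakpoint, kPa.
#' @param bp_grid Grid resolution for the breakpoint search, kPa.
#' @param continuous Constrain the two segments to meet at the breakpoint.
#' @return An object of class `segmented_fit` with elements `i1`, `s1`, `i2`,
#'   `s2`, `bp`, `sse`, `n`, `bp_fixed`, `continuous`, and the `(vpd, tr)`
#'   data used. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_two_segment <- function(data, tr = tr, vpd = vpd,
                            bp_fixed = NULL, bp_grid = 0.01,
                            continuous = FALSE) {
  y <- dplyr::pull(data, {{ tr }})
  x <- dplyr::pull(data, {{ vpd }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 4) {
    abort("need at least 4 (vpd, tr) points for a two-segment fit",
          class = "phenoeff_fit_error")
  }

  fit_at <- function(bp) .fit_segments(x, y, bp, continuous)

  if (!is.null(bp_fixed)) {
    fit <- fit_at(bp_fixed)
    if (is.null(fit)) {
      abort("fewer than 2 distinct-VPD points on one side of the fixed breakpoint",
            class = "phenoeff_fit_error")
    }
    bp <- bp_fixed
  } else {
    lo <- min(x)
    hi <- max(x)
    candidates <- seq(ceiling(lo / bp_grid) * bp_grid,
                      floor(hi / bp_grid) * bp_grid, by = bp_grid)
    fits <- lapply(candidates, fit_at)
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) {
      abort("no candidate breakpoint leaves 2 distinct-VPD points on each side",
            class = "phenoeff_fit_error")
    }
    sses <- vapply(fits[ok], function(f) f$sse, numeric(1))
    best <- which.min(sses) # first minimum -> smallest BP on ties
    fit <- fits[ok][[best]]
    bp <- candidates[ok][best]
  }

  structure(
    list(
      i1 = fit$i1, s1 = fit$s1, i2 = fit$i2, s2 = fit$s2,
      bp = bp, sse = fit$sse, n = length(x),
      bp_fixed = !is.null(bp_fixed), continuous = continuous,
      data = tibble::tibble(vpd = x, tr = y)
    ),
    class = "segmented_fit"
  )
}

# OLS on both sides of a candidate breakpoint; NULL if a side is deficient.
.fit_segments <- function(x, y, bp, continuous) {
  left <- x < bp
  xl <- x[left]
  yl <- y[left]
  xr <- x[!left]
  yr <- y[!left]
  if (length(xl) < 2 || length(xr) < 2 ||
      length(unique(xl)) < 2 || length(unique(xr)) < 2) {
    return(NULL)
  }
  if (continuous) {
    # TR = i1 + s1 * min(v, bp) + s2 * max(v - bp, 0); i2 implied
    b1 <- pmin(x, bp)
    b2 <- pmax(x - bp, 0)
    fit <- lm(y ~ b1 + b2)
    cf <- coef(fit)
    i1 <- cf[[1]]
    s1 <- cf[[2]]
    s2 <- cf[[2]] + cf[[3]]
    i2 <- i1 + (s1 - s2) * bp
    sse <- sum(fit$residuals^2)
  } else {
    fl <- .ols(xl, yl)
    fr <- .ols(xr, yr)
    i1 <- fl$intercept
    s1 <- fl$slope
    i2 <- fr$intercept
    s2 <- fr$slope
    sse <- fl$sse + fr$sse
  }
  list(i1 = i1, s1 = s1, i2 = i2, s2 = s2, sse = sse)
}

#' Common breakpoint across genotypes
#'
#' The platform protocol fits a free-breakpoint response per genotype and
#' then fixes a single common breakpoint, taken as the unweighted mean of
#' per-genotype breakpoints, for all subsequent per-plant fits.
#'
#' @param fits List of `segmented_fit` objects (one per genotype), or a
#'   numeric vector of breakpoints.
#' @return Tibble with `mean_bp`, `sd_bp` and `n`; with a single fit the
#'   standard deviation is reported as 0 and `n = 1` flags it.
#' @export
common_breakpoint <- function(fits) {
  bps <- if (is.numeric(fits)) fits else vapply(fits, function(f) f$bp, numeric(1))
  if (length(bps) == 0) {
    abort("no fits supplied", class = "phenoeff_domain_error")
  }
  tibble::tibble(
    mean_bp = mean(bps),
    sd_bp = if (length(bps) == 1) 0 else sd(bps),
    n = length(bps)
  )
}

#' Derived parameters of a two-segment VPD response
#'
#' Reporting quantities of a fitted response: TR at the breakpoint
#' (`i1 + s1 * bp`, the end of the unrestricted segment), TR at the maximum
#' observed VPD (`i2 + s2 * vpd_max`), and the slope ratio `s2 / s1`
#' quantifying transpiration restriction at high evaporative demand.
#'
#' @param fit A `segmented_fit`.
#' @param vpd_max Maximum VPD at which to evaluate the second segment, kPa;
#'   defaults to the maximum observed VPD in the fit.
#' @return Tibble with `tr_bp`, `tr_maxvpd`, `s2_s1_ratio`.
#' @export
derived_params <- function(fit, vpd_max = NULL) {
  stopifnot(inherits(fit, "segmented_fit"))
  if (is.null(vpd_max)) vpd_max <- max(fit$data$vpd)
  if (vpd_max < fit$bp) {
    abort("vpd_max must be at or above the breakpoint",
          class = "phenoeff_domain_error")
  }
  ratio <- if (is.na(fit$s1) || fit$s1 == 0) NA_real_ else fit$s2 / fit$s1
  tibble::tibble(
    tr_bp = fit$i1 + fit$s1 * fit$bp,
    tr_maxvpd = fit$i2 + fit$s2 * vpd_max,
    s2_s1_ratio = ratio
  )
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("<segmented_fit> two-segment TR ~ VPD\n")
  cat(sprintf("  below BP: TR = %.4g + %.4g * VPD\n", x$i1, x$s1))
  cat(sprintf("  at/above: TR = %.4g + %.4g * VPD\n", x$i2, x$s2))
  cat(sprintf("  BP = %.4g kPa%s, SSE = %.4g, n = %d\n",
              x$bp, if (x$bp_fixed) " (fixed)" else "", x$sse, x$n))
  invisible(x)
}

#' Predict from a two-segment fit
#'
#' @param object A `segmented_fit`.
#' @param newdata Optional data frame with a `vpd` column (defaults to the
#'   training data).
#' @param ... Unused.
#' @return Numeric vector of predicted TR.
#' @export
predict.segmented_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$vpd else newdata$vpd
  ifelse(v < object$bp,
         object$i1 + object$s1 * v,
         object$i2 + object$s2 * v)
}
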