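# Internal helpers shared across modules.

# Closed-form simple OLS of y on x. Returns list(intercept, slope, sse, n).
# Used in hot loops (segmented grid search) where lm() overhead matters.
.ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) {
    return(list(intercept = my, slope = NA_real_, sse = sum((y - my)^2), n = n))
  }
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  list(intercept = intercept, slope = slope, sse = sum(res^2), n = n)
}

# Simple linear regression with inference, tibble out.
# Shared by trait_vs_target_regression() and validate_trait().
.ols_inference <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3 || var(x) == 0 || var(y) == 0) {
    return(tibble::tibble(
      r2 = NA_real_, p_value = NA_real_, slope = NA_real_,
      intercept = NA_real_, n = n
    ))
  }
  fit <- .ols(x, y)
  r <- cor(x, y)
  r2 <- r^2
  # two-sided p for the slope via the t statistic on n - 2 df
  if (r2 >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  tibble::tibble(
    r2 = r2, p_value = p, slope = fit$slope,
    intercept = fit$intercept, n = n
  )
}

#' @importFrom stats pt
NULL

# Emit one row-level diagnostic tibble.
.diag_row <- function(table, row, field, message) {
  tibble::tibble(
    table = table, row = as.integer(row),
    field = field, message = message
  )
}

.assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing mandatory column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "phenoeff_schema_error")
  }
  invisible(df)
}
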