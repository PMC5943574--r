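#' Tidy a two-segment VPD-response fit
#'
#' @param x A `segmented_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`i1`, `s1`, `i2`, `s2`, `bp`).
#' @export
tidy.segmented_fit <- function(x, ...) {
  tibble::tibble(
    term = c("i1", "s1", "i2", "s2", "bp"),
    estimate = c(x$i1, x$s1, x$i2, x$s2, x$bp)
  )
}

#' One-row summary of a two-segment VPD-response fit
#'
#' @param x A `segmented_fit`.
#' @param ... Unused.
#' @return One-row tibble: `bp`, `sse`, `n`, `r.squared`, `bp_fixed`,
#'   `continuous`.
#' @export
glance.segmented_fit <- function(x, ...) {
  tss <- sum((x$data$tr - mean(x$data$tr))^2)
  tibble::tibble(
    bp = x$bp, sse = x$sse, n = x$n,
    r.squared = if (tss > 0) 1 - x$sse / tss else NA_real_,
    bp_fixed = x$bp_fixed, continuous = x$continuous
  )
}

#' Tidy an envelope fit
#'
#' @param x An `envelope_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`a`, `b`, `c`).
#' @export
tidy.envelope_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' One-row summary of an envelope fit
#'
#' @param x An `envelope_fit`.
#' @param ... Unused.
#' @return One-row tibble: `a`, `b`, `c`, `fraction_below`, `lambda`, `n`.
#' @export
glance.envelope_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, c = x$c,
                 fraction_below = x$fraction_below,
                 lambda = x$lambda, n = x$n)
}
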