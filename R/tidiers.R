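#' Tidy a fitted dilution curve
#'
#' @param x A `cndc_curve`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`a`, `b`) and delta-method
#'   standard errors from the log-log fit when available.
#' @method tidy cndc_curve
#' @export
tidy.cndc_curve <- function(x, ...) {
  se <- c(NA_real_, NA_real_)
  if (x$method == "loglog_ols") {
    s <- summary(x$fit)$coefficients
    # a = exp(intercept): se via delta method; b = -slope
    se <- c(x$a * s[1, 2], s[2, 2])
  } else if (inherits(x$fit, "nls")) {
    s <- summary(x$fit)$coefficients
    se <- s[c("a", "b"), 2]
  }
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b),
                 std.error = unname(se))
}

#' Glance at a fitted dilution curve
#'
#' @param x A `cndc_curve`.
#' @param ... Unused.
#' @return One-row tibble with the stratum, fit quality and biomass range.
#' @method glance cndc_curve
#' @export
glance.cndc_curve <- function(x, ...) {
  tibble::tibble(fertilizer_type = x$fertilizer_type, cut = x$cut,
                 r.squared = x$r2, n_points = x$n_points,
                 w_min = x$w_range[1], w_max = x$w_range[2],
                 method = x$method)
}

#' Tidy a full curve construction
#'
#' @param x A `cndc_fit` from [fit_cndc()].
#' @param ... Unused.
#' @return The per-stratum curves tibble.
#' @method tidy cndc_fit
#' @export
tidy.cndc_fit <- function(x, ...) x$curves

#' Glance at a full curve construction
#'
#' @param x A `cndc_fit`.
#' @param ... Unused.
#' @return One-row tibble: number of strata, total critical points, skipped
#'   dates and the range of per-stratum R^2.
#' @method glance cndc_fit
#' @export
glance.cndc_fit <- function(x, ...) {
  tibble::tibble(n_strata = nrow(x$curves),
                 n_points = sum(x$curves$n_points),
                 n_skipped = nrow(x$skipped_dates),
                 min_r2 = min(x$curves$r2), max_r2 = max(x$curves$r2))
}

#' Tidy a quadratic yield-response fit
#'
#' @param x A `cndc_yield_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`A`, `B`, `C`).
#' @method tidy cndc_yield_fit
#' @export
tidy.cndc_yield_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("C", "B", "A"), estimate = c(x$C, x$B, x$A),
                 std.error = unname(s[, 2]),
                 p.value = unname(s[, 4]))[3:1, ]
}

#' Glance at a quadratic yield-response fit
#'
#' @param x A `cndc_yield_fit`.
#' @param ... Unused.
#' @return One-row tibble with `r.squared`, the optimum and its plausibility
#'   flag.
#' @method glance cndc_yield_fit
#' @export
glance.cndc_yield_fit <- function(x, ...) {
  tibble::tibble(fertilizer_type = x$fertilizer_type,
                 year_label = x$year_label, r.squared = x$r2,
                 opt_rate = x$opt_rate, max_yield = x$max_yield,
                 opt_in_range = x$opt_in_range)
}

#' Glance at a pipeline run
#'
#' @param x A `cndc_run`.
#' @param ... Unused.
#' @return One-row tibble summarising curve quality, validation stability
#'   and warnings.
#' @method glance cndc_run
#' @export
glance.cndc_run <- function(x, ...) {
  tibble::tibble(
    n_strata = nrow(x$curves$curves),
    min_curve_r2 = min(x$curves$curves$r2),
    max_n_rmse_pct = if (is.null(x$validation)) NA_real_ else
      max(x$validation$n_rmse_pct),
    n_yield_fits = if (is.null(x$yield_fits)) 0L else nrow(x$yield_fits),
    n_warnings = length(x$warnings))
}
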