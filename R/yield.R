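#' Relative yield
#'
#' Each yield divided by the maximum of the vector, so the best treatment
#' maps to exactly 1.
#'
#' @param yields Positive numeric vector.
#' @return Values in (0, 1].
#' @examples
#' relative_yield(c(5, 10))
#' @export
relative_yield <- function(yields) {
  if (length(yields) == 0 || any(!is.finite(yields) | yields <= 0)) {
    abort("`yields` must be a nonempty vector of positive values.",
          class = "cndc_domain_error")
  }
  yields / max(yields)
}

#' Vertex of a concave quadratic yield response
#'
#' For `y = A x^2 + B x + C` with `A < 0`, returns the rate at the maximum,
#' `-B / (2A)`, and the maximum yield, `C - B^2 / (4A)`.
#'
#' @param A Quadratic coefficient (must be negative), or a fitted
#'   `cndc_yield_fit` object whose coefficients are used instead.
#' @param B,C Linear coefficient and intercept (ignored when `A` is a fit).
#' @return Named numeric `c(opt_rate, max_yield)`.
#' @examples
#' optimum(-1.14e-4, 0.04, 13.89)
#' @export
optimum <- function(A, B = NULL, C = NULL) {
  if (inherits(A, "cndc_yield_fit")) {
    B <- A$B; C <- A$C; A <- A$A
  }
  if (!is.numeric(A) || A >= 0) {
    abort("No interior maximum: quadratic coefficient A must be negative.",
          class = "cndc_domain_error")
  }
  c(opt_rate = -B / (2 * A), max_yield = C - B^2 / (4 * A))
}

#' Nitrogen saving of one fertilizer relative to another
#'
#' Percent reduction of the optimal rate: `100 * (opt_urea - opt_cru) /
#' opt_urea`. Negative when the second fertilizer needs more nitrogen.
#'
#' @param opt_urea,opt_cru Optimal N rates, kg/ha; the first must be
#'   positive.
#' @return Percent.
#' @examples
#' nitrogen_saving(200, 160) # 20
#' @export
nitrogen_saving <- function(opt_urea, opt_cru) {
  if (!is.finite(opt_urea) || opt_urea <= 0) {
    abort("`opt_urea` must be positive.", class = "cndc_domain_error")
  }
  100 * (opt_urea - opt_cru) / opt_urea
}

#' Fit a quadratic nitrogen-rate yield response
#'
#' OLS fit of `yield = A rate^2 + B rate + C`. By default replicate rows are
#' averaged per rate first (mean-level fit); set `aggregate = "replicates"`
#' to fit the replicate rows directly. The vertex is extracted when the
#' response is concave; optima beyond 1.5x the highest tested rate are
#' flagged as out of range rather than trusted.
#'
#' @param data Data frame with columns `n_rate` and `yield_t_ha` (a yield
#'   table for one fertilizer type x year).
#' @param aggregate `"means"` (default) or `"replicates"`.
#' @param fertilizer_type,year_label Optional labels stored on the result.
#' @return Object of class `cndc_yield_fit`: `A`, `B`, `C`, `r2`,
#'   `opt_rate`, `max_yield`, `opt_in_range`, `n_rates`, plus the fitted
#'   `lm`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' d <- data.frame(n_rate = c(0, 80, 160, 240),
#'                 yield_t_ha = -3.09e-4 * c(0, 80, 160, 240)^2 +
#'                   0.09 * c(0, 80, 160, 240) + 14.11)
#' fit_yield_response(d)
#' @export
fit_yield_response <- function(data, aggregate = c("means", "replicates"),
                               fertilizer_type = NA_character_,
                               year_label = NA_character_) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(data),
            all(c("n_rate", "yield_t_ha") %in% names(data)))
  if (dplyr::n_distinct(data$n_rate) < 4) {
    abort("A quadratic yield response needs at least 4 distinct N rates.",
          class = "cndc_fit_error")
  }
  df <- if (aggregate == "means") {
    data |>
      dplyr::group_by(.data$n_rate) |>
      dplyr::summarise(yield_t_ha = mean(.data$yield_t_ha), .groups = "drop")
  } else {
    data
  }
  fit <- lm(yield_t_ha ~ n_rate + I(n_rate^2), data = df)
  A <- unname(coef(fit)[3]); B <- unname(coef(fit)[2])
  C <- unname(coef(fit)[1])
  if (!is.finite(A) || A >= 0) {
    abort("No interior maximum: fitted yield response is not concave.",
          class = "cndc_fit_error")
  }
  vertex <- optimum(A, B, C)
  in_range <- vertex[["opt_rate"]] >= 0 &&
    vertex[["opt_rate"]] <= 1.5 * max(df$n_rate)
  structure(
    list(fertilizer_type = fertilizer_type, year_label = year_label,
         A = A, B = B, C = C, r2 = rsq(df$yield_t_ha, stats::residuals(fit)),
         opt_rate = vertex[["opt_rate"]], max_yield = vertex[["max_yield"]],
         opt_in_range = in_range, n_rates = dplyr::n_distinct(df$n_rate),
         data = tibble::as_tibble(df), fit = fit),
    class = "cndc_yield_fit")
}

#' @export
print.cndc_yield_fit <- function(x, ...) {
  cat(sprintf(
    "<cndc_yield_fit> %s %s: y = %.4g x^2 + %.4g x + %.4g  (R2 = %.3f)\n",
    x$fertilizer_type, x$year_label, x$A, x$B, x$C, x$r2))
  cat(sprintf("  optimum: %.2f kg/ha -> %.2f t/ha%s\n", x$opt_rate,
              x$max_yield,
              if (x$opt_in_range) "" else "  [outside plausible range]"))
  invisible(x)
}

#' Fit yield responses for every fertilizer type and year
#'
#' Convenience wrapper over [fit_yield_response()] for a full yield table.
#'
#' @param yields Yield tibble (`fertilizer_type`, `n_rate`, `year_label`,
#'   `replicate`, `yield_t_ha`).
#' @inheritParams fit_yield_response
#' @return Tibble with one row per fertilizer type x year: coefficients,
#'   `r2`, `opt_rate`, `max_yield`, `opt_in_range`.
#' @export
fit_yield_responses <- function(yields, aggregate = c("means", "replicates")) {
  aggregate <- match.arg(aggregate)
  yields <- check_yield_table(yields)
  yields |>
    dplyr::group_by(.data$fertilizer_type, .data$year_label) |>
    dplyr::group_modify(function(df, key) {
      fit <- fit_yield_response(df, aggregate,
                                fertilizer_type = key$fertilizer_type,
                                year_label = key$year_label)
      tibble::tibble(A = fit$A, B = fit$B, C = fit$C, r2 = fit$r2,
                     opt_rate = fit$opt_rate, max_yield = fit$max_yield,
                     opt_in_range = fit$opt_in_range)
    }) |>
    dplyr::ungroup()
}

#' Quadratic relationship between a diagnostic index and relative yield
#'
#' Fits `RY = c0 + c1 x + c2 x^2` where `x` is the NNI or the cumulative N
#' deficit. The sign and magnitude of the quadratic coefficient `c2`
#' measure how sharply yield responds to departures from balanced
#' nutrition.
#'
#' @param data Data frame holding the predictor column and a column `ry`.
#' @param predictor Name of the predictor column, `"nni"` or `"nand"`.
#' @return One-row tibble: `predictor`, `c0`, `c1`, `c2`, `r2`, `n`.
#'   A constant response gives zero slopes, `r2 = 0` and a warning.
#' @examples
#' d <- data.frame(nni = c(0.7, 0.9, 1.1, 1.3))
#' d$ry <- 1 - 0.5 * (d$nni - 1)^2
#' fit_relationship(d, "nni")
#' @export
fit_relationship <- function(data, predictor = c("nni", "nand")) {
  predictor <- match.arg(predictor)
  stopifnot(is.data.frame(data), "ry" %in% names(data),
            predictor %in% names(data))
  x <- data[[predictor]]; ry <- data$ry
  if (length(x) < 4) {
    abort("A quadratic relationship fit needs at least 4 points.",
          class = "cndc_fit_error")
  }
  fit <- lm(ry ~ x + I(x^2))
  r2 <- rsq(ry, stats::residuals(fit))
  if (stats::var(ry) == 0) {
    warn("Relative yield is constant; relationship R^2 reported as 0.")
    r2 <- 0
  }
  tibble::tibble(predictor = predictor,
                 c0 = unname(coef(fit)[1]), c1 = unname(coef(fit)[2]),
                 c2 = unname(coef(fit)[3]), r2 = r2, n = length(x))
}
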