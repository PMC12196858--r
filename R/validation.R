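#' Root mean square error
#'
#' @param measured,modeled Equal-length numeric vectors.
#' @return `sqrt(mean((measured - modeled)^2))`.
#' @examples
#' rmse(c(2, 4, 6), c(1, 3, 5))
#' @export
rmse <- function(measured, modeled) {
  if (length(measured) == 0 || length(measured) != length(modeled)) {
    abort("`measured` and `modeled` must be nonempty vectors of equal length.",
          class = "cndc_domain_error")
  }
  sqrt(mean((measured - modeled)^2))
}

#' Normalized RMSE in percent
#'
#' RMSE divided by the mean of the measured values, times 100.
#'
#' @inheritParams rmse
#' @return Percent.
#' @examples
#' n_rmse(c(2, 4, 6), c(1, 3, 5)) # 25
#' @export
n_rmse <- function(measured, modeled) {
  s <- mean(measured)
  if (!is.finite(s) || s <= 0) {
    abort("Mean of `measured` must be positive for a normalized RMSE.",
          class = "cndc_domain_error")
  }
  100 * rmse(measured, modeled) / s
}

#' Model stability class from the normalized RMSE
#'
#' Standard crop-model rubric: below 10% excellent, 10-20% good, 20-30%
#' fair, 30% and above poor. Boundary values are assigned upward (10% is
#' good, 20% fair, 30% poor).
#'
#' @param n_rmse_pct Normalized RMSE in percent, nonnegative. Vectorized.
#' @return Character vector with values `"excellent"`, `"good"`, `"fair"`,
#'   `"poor"`.
#' @examples
#' stability_class(c(8, 15, 25, 35))
#' @export
stability_class <- function(n_rmse_pct) {
  if (any(!is.finite(n_rmse_pct) | n_rmse_pct < 0)) {
    abort("`n_rmse_pct` must be nonnegative.", class = "cndc_domain_error")
  }
  dplyr::case_when(
    n_rmse_pct < 10 ~ "excellent",
    n_rmse_pct < 20 ~ "good",
    n_rmse_pct < 30 ~ "fair",
    .default = "poor")
}

#' Agreement line between measured and modeled values
#'
#' OLS of modeled on measured; perfect agreement gives slope 1, intercept 0
#' and R^2 = 1 (the 1:1 line).
#'
#' @inheritParams rmse
#' @return List with `slope`, `intercept`, `r2`.
#' @examples
#' one_to_one_fit(1:5, 1:5)
#' @export
one_to_one_fit <- function(measured, modeled) {
  if (length(measured) < 3 || length(measured) != length(modeled)) {
    abort("An agreement fit needs at least 3 paired values.",
          class = "cndc_domain_error")
  }
  fit <- lm(modeled ~ measured)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = rsq(modeled, stats::residuals(fit)))
}

#' Validate fitted dilution curves against an independent season
#'
#' Re-derives per-date critical N points from the validation season with the
#' same ANOVA/LSD construction procedure, predicts the critical
#' concentration from the supplied (construction-season) curves at each
#' validation date's maximum biomass, and compares the two series per
#' fertilizer type x cut via RMSE, normalized RMSE, a stability class, and a
#' measured-vs-modeled agreement line.
#'
#' @param curves A `cndc_fit` (or its `curves` tibble) from the
#'   construction season.
#' @param data A [cndc_trial()] or observation tibble for the validation
#'   season.
#' @param config A [cndc_config()].
#' @return Tibble with one row per stratum: `n`, `s_mean` (mean measured
#'   critical concentration, percent), `rmse`, `n_rmse_pct`, `stability`,
#'   `slope_11`, `intercept_11`, `r2_11` (agreement-line statistics, `NA`
#'   when fewer than 3 dates are usable).
#' @examples
#' fit <- fit_cndc(generate_trial(synthetic_trial_spec(seed = 1)))
#' val <- generate_trial(synthetic_trial_spec(seed = 2))
#' validate_curves(fit, val)
#' @export
validate_curves <- function(curves, data, config = cndc_config()) {
  val_fit <- fit_cndc(data, config)
  tab <- if (inherits(curves, "cndc_fit")) curves$curves else
    tibble::as_tibble(curves)

  pts_all <- val_fit$critical_points
  uncovered <- dplyr::anti_join(
    dplyr::distinct(pts_all, .data$fertilizer_type, .data$cut), tab,
    by = c("fertilizer_type", "cut"))
  if (nrow(uncovered) > 0) {
    warn(sprintf(
      "%d validation stratum/strata have no construction-season curve and are dropped.",
      nrow(uncovered)))
  }

  pts_all |>
    dplyr::semi_join(tab, by = c("fertilizer_type", "cut")) |>
    dplyr::group_by(.data$fertilizer_type, .data$cut) |>
    dplyr::group_modify(function(pts, key) {
      curve <- curve_for_stratum(tab, key$fertilizer_type, key$cut)
      modeled <- as.numeric(predict_nc(curve, pts$w_max))
      measured <- pts$nc
      one <- if (nrow(pts) >= 3) one_to_one_fit(measured, modeled) else
        list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_)
      tibble::tibble(
        n = nrow(pts), s_mean = mean(measured),
        rmse = rmse(measured, modeled),
        n_rmse_pct = n_rmse(measured, modeled),
        stability = stability_class(n_rmse(measured, modeled)),
        slope_11 = one$slope, intercept_11 = one$intercept, r2_11 = one$r2)
    }) |>
    dplyr::ungroup()
}
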