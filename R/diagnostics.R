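#' Nitrogen nutrition index
#'
#' Ratio of the measured plant N concentration to the critical concentration
#' at the same biomass: 1 means adequate nutrition, below 1 deficit, above 1
#' surplus.
#'
#' @param ni Measured N concentration, percent.
#' @param nc Critical N concentration, percent; must be positive.
#' @return `ni / nc`, dimensionless. Vectorized.
#' @examples
#' compute_nni(3.5, 2.8)
#' @export
compute_nni <- function(ni, nc) {
  if (any(!is.finite(nc) | nc <= 0)) {
    abort("Critical concentration `nc` must be positive.",
          class = "cndc_domain_error")
  }
  ni / nc
}

#' Aboveground nitrogen accumulation
#'
#' Converts a concentration (percent of dry mass) and a biomass (t/ha) to an
#' N mass per hectare: `(conc / 100) * (w * 1000) = 10 * conc * w` kg/ha.
#'
#' @param conc N concentration, percent (>= 0).
#' @param w Aboveground biomass, t/ha (>= 0).
#' @return N accumulation, kg/ha. Vectorized.
#' @examples
#' n_accumulation(3, 7) # 210 kg/ha
#' @export
n_accumulation <- function(conc, w) {
  if (any(!is.finite(conc) | conc < 0) || any(!is.finite(w) | w < 0)) {
    abort("`conc` and `w` must be nonnegative.", class = "cndc_domain_error")
  }
  10 * conc * w
}

#' Cumulative nitrogen deficit
#'
#' Difference between the N the crop would hold at the critical
#' concentration and the N it actually holds:
#' `10 * w * (Nc(w) - Ni)` kg/ha. Positive values mean the crop accumulated
#' less N than the critical requirement (deficit), negative values surplus.
#'
#' @param curve A fitted dilution curve (see [predict_nc()]).
#' @param w Aboveground biomass, t/ha; positive.
#' @param ni Measured N concentration, percent.
#' @return Deficit in kg/ha. Vectorized over `w` and `ni`.
#' @examples
#' compute_nand(list(a = 3.0, b = 0), 7, 2.7) # +21 kg/ha
#' @export
compute_nand <- function(curve, w, ni) {
  nc <- predict_nc(curve, w)
  10 * w * (as.numeric(nc) - ni)
}

#' Label a nutrition status from the NNI
#'
#' @param nni Nitrogen nutrition index, positive.
#' @param tol Half-width of the "appropriate" band around 1.
#' @return Character vector with values `"deficit"`, `"appropriate"` or
#'   `"surplus"`.
#' @examples
#' classify_status(c(0.65, 1.0, 1.25))
#' @export
classify_status <- function(nni, tol = 0.05) {
  stopifnot(tol >= 0)
  dplyr::case_when(
    nni > 1 + tol ~ "surplus",
    nni < 1 - tol ~ "deficit",
    .default = "appropriate")
}

#' Per-treatment nitrogen diagnostics
#'
#' Computes, for every treatment x cut x sampling date, the treatment-mean
#' biomass and N concentration, the model-critical concentration, the NNI,
#' the actual and critical N accumulations, the cumulative deficit and a
#' status label. Predictions outside the fitted biomass range are flagged.
#'
#' @param data A [cndc_trial()] or observation tibble.
#' @param curves A `cndc_fit` or its `curves` tibble; must cover every
#'   fertilizer type x cut present in `data`.
#' @param config A [cndc_config()]; `nni_tolerance` controls the
#'   "appropriate" band.
#' @return Tibble with one row per fertilizer type x N rate x cut x date:
#'   `w`, `ni`, `nc_pred`, `nni`, `ncand`, `niand`, `nand`, `status`,
#'   `extrapolated`.
#' @examples
#' ds <- generate_trial(synthetic_trial_spec(seed = 3))
#' fit <- fit_cndc(ds)
#' head(diagnostic_series(ds, fit))
#' @export
diagnostic_series <- function(data, curves, config = cndc_config()) {
  obs <- if (inherits(data, "cndc_trial")) data$observations else
    check_observation_table(data)
  tab <- if (inherits(curves, "cndc_fit")) curves$curves else
    tibble::as_tibble(curves)

  need <- dplyr::distinct(obs, .data$fertilizer_type, .data$cut)
  missing <- dplyr::anti_join(need, tab, by = c("fertilizer_type", "cut"))
  if (nrow(missing) > 0) {
    abort(sprintf("No fitted curve for stratum (%s, cut %s).",
                  missing$fertilizer_type[1], missing$cut[1]),
          class = "cndc_missing_curve_error")
  }

  obs |>
    dplyr::group_by(.data$fertilizer_type, .data$n_rate, .data$cut,
                    .data$date_index) |>
    dplyr::summarise(w = mean(.data$biomass_w), ni = mean(.data$n_conc),
                     .groups = "drop") |>
    dplyr::inner_join(tab, by = c("fertilizer_type", "cut")) |>
    dplyr::mutate(
      nc_pred = .data$a * .data$w^(-.data$b),
      extrapolated = .data$w < .data$w_min | .data$w > .data$w_max,
      nni = compute_nni(.data$ni, .data$nc_pred),
      ncand = n_accumulation(.data$nc_pred, .data$w),
      niand = n_accumulation(.data$ni, .data$w),
      nand = .data$ncand - .data$niand,
      status = classify_status(.data$nni, config$nni_tolerance)) |>
    dplyr::select("fertilizer_type", "n_rate", "cut", "date_index", "w",
                  "ni", "nc_pred", "nni", "ncand", "niand", "nand", "status",
                  "extrapolated")
}
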