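#' Run the full nitrogen-diagnostics pipeline
#'
#' Orchestrates every stage on a construction-season dataset: dataset
#' checks, dilution-curve construction, optional cross-season validation,
#' per-treatment NNI / N-deficit diagnostics, quadratic yield-response fits
#' with optimal rates, and diagnostic-vs-relative-yield relationship fits.
#' Optionally writes the tables as CSV plus a machine-readable JSON summary.
#'
#' @param construction A [cndc_trial()] for the construction season.
#' @param validation Optional [cndc_trial()] (or observation tibble) for an
#'   independent season used to validate the curves.
#' @param yields Optional yield tibble; defaults to the yields carried by
#'   `construction`.
#' @param config A [cndc_config()].
#' @param out_dir Optional directory; when given, writes `curves.csv`,
#'   `critical_points.csv`, `skipped_dates.csv`, `diagnostics.csv`,
#'   `yield_fits.csv`, `relationships.csv`, `validation.csv` and
#'   `summary.json`.
#' @return Object of class `cndc_run`: `curves` (the `cndc_fit`),
#'   `validation` (tibble or `NULL`), `diagnostics`, `yield_fits`,
#'   `relationships`, `optima`, `warnings`, `config`. Supports [glance()].
#' @examples
#' ds <- generate_trial(synthetic_trial_spec(seed = 11))
#' run <- run_cndc_pipeline(ds)
#' glance(run)
#' @export
run_cndc_pipeline <- function(construction, validation = NULL, yields = NULL,
                              config = cndc_config(), out_dir = NULL) {
  if (!inherits(construction, "cndc_trial")) {
    construction <- cndc_trial(construction)
  }
  warnings <- validate_dataset(construction, config)

  fit <- fit_cndc(construction, config)
  if (nrow(fit$skipped_dates) > 0) {
    warnings <- c(warnings, sprintf(
      "Skipped %s cut %d date %d: %s", fit$skipped_dates$fertilizer_type,
      fit$skipped_dates$cut, fit$skipped_dates$date_index,
      fit$skipped_dates$reason))
  }

  if (nrow(fit$skipped_strata) > 0) {
    warnings <- c(warnings, sprintf(
      "Stratum %s cut %d not fitted: %s.", fit$skipped_strata$fertilizer_type,
      fit$skipped_strata$cut, fit$skipped_strata$reason))
  }

  val <- NULL
  if (!is.null(validation)) {
    val <- validate_curves(fit, validation, config)
  }

  diag_obs <- dplyr::semi_join(construction$observations, fit$curves,
                               by = c("fertilizer_type", "cut"))
  diagnostics <- diagnostic_series(diag_obs, fit, config)
  n_extra <- sum(diagnostics$extrapolated)
  if (n_extra > 0) {
    warnings <- c(warnings, sprintf(
      "%d diagnostic record(s) extrapolate beyond the fitted biomass range.",
      n_extra))
  }

  yields <- yields %||% construction$yields
  yield_fits <- NULL; optima <- NULL; relationships <- NULL
  if (!is.null(yields)) {
    yield_fits <- fit_yield_responses(yields)
    optima <- dplyr::select(yield_fits, "fertilizer_type", "year_label",
                            "opt_rate", "max_yield")
    relationships <- relationship_fits(diagnostics, yields)
  }

  run <- structure(
    list(curves = fit, validation = val, diagnostics = diagnostics,
         yield_fits = yield_fits, relationships = relationships,
         optima = optima, warnings = warnings, config = config,
         version = as.character(utils::packageVersion("cndc"))),
    class = "cndc_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Per-treatment NNI and Nand (averaged over cuts and dates) against the
# treatment's relative yield, fitted per fertilizer type.
relationship_fits <- function(diagnostics, yields) {
  ry_tab <- yields |>
    dplyr::group_by(.data$fertilizer_type, .data$n_rate) |>
    dplyr::summarise(yield = mean(.data$yield_t_ha), .groups = "drop_last") |>
    dplyr::mutate(ry = relative_yield(.data$yield)) |>
    dplyr::ungroup()
  diag_tab <- diagnostics |>
    dplyr::group_by(.data$fertilizer_type, .data$n_rate) |>
    dplyr::summarise(nni = mean(.data$nni), nand = mean(.data$nand),
                     .groups = "drop")
  joined <- dplyr::inner_join(diag_tab, ry_tab,
                              by = c("fertilizer_type", "n_rate"))
  joined |>
    dplyr::group_by(.data$fertilizer_type) |>
    dplyr::group_modify(function(df, key) {
      dplyr::bind_rows(fit_relationship(df, "nni"),
                       fit_relationship(df, "nand"))
    }) |>
    dplyr::ungroup()
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fit <- run$curves
  readr::write_csv(fit$curves, file.path(out_dir, "curves.csv"))
  readr::write_csv(fit$critical_points,
                   file.path(out_dir, "critical_points.csv"))
  if (nrow(fit$skipped_dates) > 0) {
    readr::write_csv(fit$skipped_dates,
                     file.path(out_dir, "skipped_dates.csv"))
  }
  readr::write_csv(run$diagnostics, file.path(out_dir, "diagnostics.csv"))
  if (!is.null(run$validation)) {
    readr::write_csv(run$validation, file.path(out_dir, "validation.csv"))
  }
  if (!is.null(run$yield_fits)) {
    readr::write_csv(run$yield_fits, file.path(out_dir, "yield_fits.csv"))
    readr::write_csv(run$relationships,
                     file.path(out_dir, "relationships.csv"))
  }
  summary <- list(
    version = run$version,
    config = unclass(run$config),
    curves = fit$curves,
    validation = run$validation,
    status_counts = dplyr::count(run$diagnostics, .data$fertilizer_type,
                                 .data$n_rate, .data$status),
    yield_fits = run$yield_fits,
    warnings = run$warnings)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.cndc_run <- function(x, ...) {
  cat("<cndc_run>\n")
  print(x$curves$curves)
  if (!is.null(x$validation)) {
    cat("validation:\n"); print(x$validation)
  }
  if (!is.null(x$optima)) {
    cat("optima:\n"); print(x$optima)
  }
  if (length(x$warnings) > 0) {
    cat(sprintf("%d warning(s); see $warnings.\n", length(x$warnings)))
  }
  invisible(x)
}
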