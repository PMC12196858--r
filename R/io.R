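obs_cols <- c("fertilizer_type", "n_rate", "cut", "date_index", "replicate",
              "biomass_w", "n_conc")
yield_cols <- c("fertilizer_type", "n_rate", "year_label", "replicate",
                "yield_t_ha")

#' Trial dataset container
#'
#' Bundles the two tidy tables of a multi-cut fertilizer trial: per-sampling
#' observations (biomass in t/ha and plant N concentration in percent of dry
#' mass) and per-plot seasonal yields.
#'
#' @param observations Tibble with columns `fertilizer_type`, `n_rate`
#'   (kg/ha), `cut`, `date_index`, `replicate`, `biomass_w` (t/ha), `n_conc`
#'   (percent).
#' @param yields Optional tibble with columns `fertilizer_type`, `n_rate`,
#'   `year_label`, `replicate`, `yield_t_ha`.
#' @param metadata Named list of free-form annotations (site, year, seed...).
#'
#' @return A list of class `cndc_trial` with elements `observations`,
#'   `yields` and `metadata`.
#' @export
cndc_trial <- function(observations, yields = NULL, metadata = list()) {
  observations <- check_observation_table(observations)
  if (!is.null(yields)) yields <- check_yield_table(yields)
  structure(list(observations = observations, yields = yields,
                 metadata = metadata),
            class = "cndc_trial")
}

#' @export
print.cndc_trial <- function(x, ...) {
  cat("<cndc_trial>\n")
  cat(sprintf("  observations: %d rows (%d strata)\n",
              nrow(x$observations),
              nrow(dplyr::distinct(x$observations, .data$fertilizer_type,
                                   .data$cut, .data$date_index))))
  if (is.null(x$yields)) {
    cat("  yields:       none\n")
  } else {
    cat(sprintf("  yields:       %d rows\n", nrow(x$yields)))
  }
  if (length(x$metadata) > 0) {
    cat("  metadata:     ", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

check_observation_table <- function(df) {
  df <- check_columns(df, obs_cols, "observation")
  check_positive(df, "biomass_w")
  bad <- which(!is.finite(df$n_conc) | df$n_conc <= 0 | df$n_conc >= 100)
  if (length(bad) > 0) {
    abort(sprintf(
      "Column `n_conc` must lie strictly between 0 and 100 (percent); first offending row: %d.",
      bad[1]), class = "cndc_validation_error")
  }
  check_nonneg(df, "n_rate")
  key <- df[c("fertilizer_type", "n_rate", "cut", "date_index", "replicate")]
  if (anyDuplicated(key) > 0) {
    abort(sprintf(
      "Duplicate (fertilizer_type, n_rate, cut, date_index, replicate) key at row %d.",
      anyDuplicated(key)), class = "cndc_validation_error")
  }
  tibble::as_tibble(df)
}

check_yield_table <- function(df) {
  df <- check_columns(df, yield_cols, "yield")
  check_positive(df, "yield_t_ha")
  check_nonneg(df, "n_rate")
  tibble::as_tibble(df)
}

check_columns <- function(df, wanted, what) {
  if (!is.data.frame(df)) {
    abort(sprintf("A %s table must be a data frame.", what),
          class = "cndc_schema_error")
  }
  names(df) <- tolower(names(df))
  missing <- setdiff(wanted, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s table is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")),
          class = "cndc_schema_error")
  }
  df[wanted]
}

check_positive <- function(df, col) {
  v <- df[[col]]
  bad <- which(!is.finite(v) | v <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Column `%s` must be a positive number; first offending row: %d.",
                  col, bad[1]), class = "cndc_validation_error")
  }
  invisible(df)
}

check_nonneg <- function(df, col) {
  v <- df[[col]]
  bad <- which(!is.finite(v) | v < 0)
  if (length(bad) > 0) {
    abort(sprintf("Column `%s` must be nonnegative; first offending row: %d.",
                  col, bad[1]), class = "cndc_validation_error")
  }
  invisible(df)
}

#' Read a tidy trial table from CSV
#'
#' Reads either an observation table or a yield table in the package's CSV
#' dialect (UTF-8, comma separator, `.` decimal mark, lowercase headers) and
#' validates it row by row.
#'
#' @param path Path to the CSV file.
#' @param schema `"observations"` or `"yields"`.
#' @return A validated tibble.
#' @seealso [write_trial()] for the inverse operation.
#' @export
read_observations <- function(path, schema = c("observations", "yields")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "cndc_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (schema == "observations") check_observation_table(df)
  else check_yield_table(df)
}

#' Write a trial dataset to CSV
#'
#' Writes `observations.csv` (and `yields.csv` when present) into `dir`,
#' using the same dialect that [read_observations()] expects, so a
#' write-read round trip reproduces the dataset.
#'
#' @param ds A [cndc_trial()] dataset.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(ds, dir) {
  stopifnot(inherits(ds, "cndc_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, "observations.csv")
  readr::write_csv(ds$observations, paths[1])
  if (!is.null(ds$yields)) {
    paths <- c(paths, file.path(dir, "yields.csv"))
    readr::write_csv(ds$yields, paths[2])
  }
  invisible(paths)
}

#' Read a trial dataset from a directory
#'
#' @param dir Directory holding `observations.csv` and optionally
#'   `yields.csv` as written by [write_trial()].
#' @param metadata Named list attached to the returned dataset.
#' @return A [cndc_trial()] dataset.
#' @export
read_trial <- function(dir, metadata = list()) {
  obs <- read_observations(file.path(dir, "observations.csv"), "observations")
  ypath <- file.path(dir, "yields.csv")
  yields <- if (file.exists(ypath)) read_observations(ypath, "yields") else NULL
  cndc_trial(obs, yields, metadata)
}

#' Pre-flight checks on a trial dataset
#'
#' Flags design weaknesses that do not stop the analysis but degrade it:
#' strata with fewer than 3 replicates, sampling dates with a single N rate,
#' and cuts with fewer than 3 sampling dates (too few critical points for a
#' power-law fit). An empty dataset is an error, not a warning.
#'
#' @param ds A [cndc_trial()] dataset.
#' @param config A [cndc_config()] (reserved for future checks).
#' @return Character vector of warnings, possibly empty.
#' @export
validate_dataset <- function(ds, config = cndc_config()) {
  stopifnot(inherits(ds, "cndc_trial"))
  obs <- ds$observations
  if (nrow(obs) == 0) {
    abort("Dataset contains no observations.", class = "cndc_validation_error")
  }
  warnings <- character()

  by_date <- obs |>
    dplyr::group_by(.data$fertilizer_type, .data$cut, .data$date_index) |>
    dplyr::summarise(
      n_rates = dplyr::n_distinct(.data$n_rate),
      min_reps = min(table(.data$n_rate)),
      .groups = "drop")
  for (i in which(by_date$min_reps < 3)) {
    warnings <- c(warnings, sprintf(
      "Stratum %s cut %d date %d has fewer than 3 replicates in some treatment.",
      by_date$fertilizer_type[i], by_date$cut[i], by_date$date_index[i]))
  }
  for (i in which(by_date$n_rates < 2)) {
    warnings <- c(warnings, sprintf(
      "Stratum %s cut %d date %d has a single N rate; classification impossible.",
      by_date$fertilizer_type[i], by_date$cut[i], by_date$date_index[i]))
  }

  by_cut <- obs |>
    dplyr::group_by(.data$fertilizer_type, .data$cut) |>
    dplyr::summarise(n_dates = dplyr::n_distinct(.data$date_index),
                     .groups = "drop")
  for (i in which(by_cut$n_dates < 3)) {
    warnings <- c(warnings, sprintf(
      "Cut %d (%s) has only %d sampling date(s); a power-law fit needs at least 3 critical points.",
      by_cut$cut[i], by_cut$fertilizer_type[i], by_cut$n_dates[i]))
  }
  warnings
}
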