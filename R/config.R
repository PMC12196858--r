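#' Analysis configuration
#'
#' Bundles the knobs shared by every pipeline stage. Defaults follow common
#' agronomic practice: treatment classification at `p = 0.05`, log-log
#' least-squares for the dilution-curve fit, and a +/-0.05 band around
#' `NNI = 1` inside which nutrition is labelled "appropriate".
#'
#' @param alpha Significance level for the per-date ANOVA and the LSD
#'   threshold used to split treatments into nitrogen-limited and
#'   non-limited groups. Must lie strictly inside (0, 1).
#' @param fit_method How the power law `Nc = a * W^-b` is fitted:
#'   `"loglog_ols"` (ordinary least squares on the log-log scale, the
#'   default, bit-reproducible) or `"nls"` (nonlinear least squares on the
#'   original scale, initialised from the log-log estimates).
#' @param nni_tolerance Half-width of the band around `NNI = 1` that is
#'   still reported as appropriate nutrition. Nonnegative.
#' @param min_limited_points Minimum number of nitrogen-limited treatments
#'   a sampling date must have for its biomass-concentration regression to
#'   be attempted. At least 2.
#' @param seed Integer seed recorded with the run.
#'
#' @return A list of class `cndc_config`.
#' @examples
#' cndc_config()
#' cndc_config(fit_method = "nls", nni_tolerance = 0.1)
#' @export
cndc_config <- function(alpha = 0.05,
                        fit_method = c("loglog_ols", "nls"),
                        nni_tolerance = 0.05,
                        min_limited_points = 2L,
                        seed = 1L) {
  fit_method <- match.arg(fit_method)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number strictly between 0 and 1.",
          class = "cndc_config_error")
  }
  if (!is.numeric(nni_tolerance) || length(nni_tolerance) != 1 ||
      is.na(nni_tolerance) || nni_tolerance < 0) {
    abort("`nni_tolerance` must be a single nonnegative number.",
          class = "cndc_config_error")
  }
  min_limited_points <- as.integer(min_limited_points)
  if (is.na(min_limited_points) || min_limited_points < 2L) {
    abort("`min_limited_points` must be an integer >= 2.",
          class = "cndc_config_error")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) {
    abort("`seed` must be an integer.", class = "cndc_config_error")
  }
  structure(
    list(alpha = alpha, fit_method = fit_method,
         nni_tolerance = nni_tolerance,
         min_limited_points = min_limited_points, seed = seed),
    class = "cndc_config"
  )
}

#' Load a configuration file
#'
#' Reads a YAML key-value file holding any subset of the [cndc_config()]
#' fields; unset keys fall back to the documented defaults. A missing or
#' `NULL` path returns the defaults unchanged.
#'
#' @param path Path to a YAML file, or `NULL`.
#' @return A `cndc_config` object.
#' @examples
#' load_config(NULL)
#' @export
load_config <- function(path = NULL) {
  if (is.null(path) || !file.exists(path)) {
    return(cndc_config())
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("alpha", "fit_method", "nni_tolerance", "min_limited_points",
             "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warn(paste0("Ignoring unknown config keys: ",
                paste(unknown, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(cndc_config, raw)
}

#' @export
print.cndc_config <- function(x, ...) {
  cat("<cndc_config>\n")
  cat(sprintf("  alpha:              %g\n", x$alpha))
  cat(sprintf("  fit_method:         %s\n", x$fit_method))
  cat(sprintf("  nni_tolerance:      %g\n", x$nni_tolerance))
  cat(sprintf("  min_limited_points: %d\n", x$min_limited_points))
  cat(sprintf("  seed:               %d\n", x$seed))
  invisible(x)
}
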