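#' Classify treatments as nitrogen-limited or non-limited at one date
#'
#' One-way ANOVA of replicate biomass across N rates, followed by an LSD
#' screen against the best-performing treatment: a rate is non-limited when
#' its mean biomass sits within one least significant difference of the
#' maximum treatment mean, i.e. further fertilizer did not significantly
#' raise biomass. If the overall ANOVA is not significant at `alpha`, every
#' rate is non-limited and the date carries no information for the
#' dilution-curve regression.
#'
#' @param obs Observation rows for a single fertilizer type, cut and
#'   sampling date (columns `n_rate`, `replicate`, `biomass_w` at least).
#' @param alpha Significance level for the ANOVA and the LSD.
#' @return One-row tibble: `anova_f`, `anova_p`, `lsd`, and list-columns
#'   `limited` / `non_limited` holding the rate sets.
#' @examples
#' obs <- tidyr::expand_grid(n_rate = c(0, 80, 160, 240), replicate = 1:3)
#' obs$biomass_w <- c(2, 3, 4, 4)[match(obs$n_rate, c(0, 80, 160, 240))] +
#'   0.05 * (obs$replicate - 2)
#' classify_date(obs)
#' @export
classify_date <- function(obs, alpha = 0.05) {
  stopifnot(is.data.frame(obs))
  counts <- table(obs$n_rate)
  if (length(counts) < 2) {
    abort("Classification needs at least 2 N rates at a sampling date.",
          class = "cndc_classification_error")
  }
  if (any(counts < 2)) {
    abort("Classification needs replicate data: some treatment has a single plot.",
          class = "cndc_classification_error")
  }
  if (length(unique(counts)) == 1) {
    r <- unname(counts[1])
  } else {
    r <- length(counts) / sum(1 / counts)  # harmonic mean
    warn("Unbalanced replicate counts; LSD uses the harmonic mean of group sizes.")
  }
  fit <- aov(biomass_w ~ factor(n_rate), data = obs)
  tab <- summary(fit)[[1]]
  f_value <- tab$`F value`[1]
  p_value <- tab$`Pr(>F)`[1]
  ms_within <- tab$`Mean Sq`[2]
  df_within <- tab$Df[2]
  lsd <- qt(1 - alpha / 2, df_within) * sqrt(2 * ms_within / r)

  means <- tapply(obs$biomass_w, obs$n_rate, mean)
  rates <- as.numeric(names(means))
  if (p_value >= alpha) {
    non_limited <- rates
  } else {
    non_limited <- rates[max(means) - means <= lsd]
  }
  tibble::tibble(
    anova_f = f_value, anova_p = p_value, lsd = lsd,
    limited = list(sort(setdiff(rates, non_limited))),
    non_limited = list(sort(non_limited)))
}

#' Linear regression of N concentration on biomass for limited treatments
#'
#' @param points Data frame of treatment means with columns `w` (t/ha) and
#'   `n_conc` (percent), one row per nitrogen-limited treatment.
#' @param min_points Minimum number of points required.
#' @return List with `slope`, `intercept`, `r2`.
#' @export
limited_regression <- function(points, min_points = 2L) {
  stopifnot(is.data.frame(points), all(c("w", "n_conc") %in% names(points)))
  if (nrow(points) < min_points) {
    abort(sprintf("Need at least %d nitrogen-limited points, got %d.",
                  min_points, nrow(points)),
          class = "cndc_regression_error")
  }
  if (dplyr::n_distinct(points$w) < 2) {
    abort("All limited-group biomasses are identical; regression is singular.",
          class = "cndc_regression_error")
  }
  fit <- lm(n_conc ~ w, data = points)
  res <- stats::residuals(fit)
  ss_tot <- sum((points$n_conc - mean(points$n_conc))^2)
  r2 <- if (ss_tot == 0) {
    if (sum(res^2) < 1e-12) 1 else 0
  } else {
    1 - sum(res^2) / ss_tot
  }
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2)
}

#' Critical N point for one sampling date
#'
#' The maximum attainable biomass is the mean of the non-limited treatment
#' means; the critical concentration is the limited-group regression line
#' evaluated at that biomass.
#'
#' @param classification One-row tibble from [classify_date()].
#' @param regression List from [limited_regression()].
#' @param means Treatment means for the date: data frame with `n_rate`, `w`.
#' @return One-row tibble `w_max`, `nc`, `slope`, `intercept`, `r2_limited`,
#'   or `NULL` with a warning condition if the critical concentration is
#'   non-physical (<= 0).
#' @export
critical_point <- function(classification, regression, means) {
  non_lim <- classification$non_limited[[1]]
  if (length(non_lim) == 0) {
    abort("No non-limited treatment at this date.",
          class = "cndc_construction_error")
  }
  w_max <- mean(means$w[means$n_rate %in% non_lim])
  nc <- regression$slope * w_max + regression$intercept
  if (!is.finite(nc) || nc <= 0) {
    return(NULL)
  }
  tibble::tibble(w_max = w_max, nc = nc, slope = regression$slope,
                 intercept = regression$intercept,
                 r2_limited = regression$r2)
}

#' Fit the critical nitrogen dilution curve Nc = a * W^-b
#'
#' @param points Data frame of critical points with columns `w_max` (or `w`)
#'   and `nc`; at least 3 rows with positive values.
#' @param method `"loglog_ols"` (default): OLS of `log(nc)` on `log(w)`,
#'   `a = exp(intercept)`, `b = -slope`, with R^2 on the log-log scale.
#'   `"nls"`: nonlinear least squares on the original scale initialised from
#'   the log-log estimates, R^2 on the original scale.
#' @param fertilizer_type,cut Optional stratum labels stored on the result.
#' @return An object of class `cndc_curve`: fields `a`, `b`, `r2`,
#'   `n_points`, `w_range`, `method`, plus the points and the underlying fit.
#'   Supports [tidy()], [glance()], [predict_nc()] and [autoplot()].
#' @examples
#' w <- c(2, 4, 6, 8)
#' pts <- data.frame(w_max = w, nc = 3.41 * w^-0.2)
#' fit_dilution_curve(pts)
#' @export
fit_dilution_curve <- function(points, method = c("loglog_ols", "nls"),
                               fertilizer_type = NA_character_,
                               cut = NA_integer_) {
  method <- match.arg(method)
  stopifnot(is.data.frame(points))
  if (!"w_max" %in% names(points) && "w" %in% names(points)) {
    points$w_max <- points$w
  }
  stopifnot(all(c("w_max", "nc") %in% names(points)))
  if (nrow(points) < 3) {
    abort(sprintf(
      "Dilution-curve fit for stratum (%s, cut %s) needs >= 3 critical points, got %d.",
      fertilizer_type, cut, nrow(points)), class = "cndc_fit_error")
  }
  if (any(points$w_max <= 0) || any(points$nc <= 0)) {
    abort("Critical points must have positive biomass and concentration.",
          class = "cndc_fit_error")
  }

  log_fit <- lm(log(nc) ~ log(w_max), data = points)
  a0 <- exp(unname(coef(log_fit)[1]))
  b0 <- -unname(coef(log_fit)[2])

  if (method == "loglog_ols") {
    a <- a0; b <- b0
    r2 <- rsq(log(points$nc), stats::residuals(log_fit))
    fit <- log_fit
  } else {
    # scaleOffset keeps the convergence test meaningful on zero-residual data
    fit <- nls(nc ~ a * w_max^(-b), data = points,
               start = list(a = a0, b = b0),
               control = stats::nls.control(maxiter = 100, scaleOffset = 1))
    a <- unname(coef(fit)[["a"]])
    b <- unname(coef(fit)[["b"]])
    r2 <- rsq(points$nc, stats::residuals(fit))
  }
  structure(
    list(fertilizer_type = fertilizer_type, cut = cut, a = a, b = b, r2 = r2,
         n_points = nrow(points),
         w_range = range(points$w_max), method = method,
         points = tibble::as_tibble(points[c("w_max", "nc")]), fit = fit),
    class = "cndc_curve")
}

#' @export
print.cndc_curve <- function(x, ...) {
  cat(sprintf(
    "<cndc_curve> %s cut %s: Nc = %.4g * W^-%.4g  (R2 = %.4f, n = %d, W in [%.2f, %.2f])\n",
    x$fertilizer_type, x$cut, x$a, x$b, x$r2, x$n_points,
    x$w_range[1], x$w_range[2]))
  invisible(x)
}

#' Predict the critical N concentration at a given biomass
#'
#' Evaluates `a * W^-b`. Predictions outside the biomass range the curve was
#' fitted on are still returned but flagged in the `"extrapolated"`
#' attribute.
#'
#' @param curve A `cndc_curve`, or any list/one-row data frame with fields
#'   `a` and `b` (and optionally `w_min`/`w_max` or `w_range`).
#' @param w Positive biomass value(s), t/ha.
#' @return Numeric vector of critical concentrations (percent) with a
#'   logical attribute `"extrapolated"`.
#' @examples
#' predict_nc(list(a = 3.13, b = 0.35), 1)
#' @export
predict_nc <- function(curve, w) {
  if (is.data.frame(curve)) {
    stopifnot(nrow(curve) == 1)
    curve <- as.list(curve)
  }
  if (any(!is.finite(w) | w <= 0)) {
    abort("Biomass `w` must be positive.", class = "cndc_domain_error")
  }
  nc <- curve$a * w^(-curve$b)
  rng <- curve$w_range %||% c(curve$w_min %||% NA_real_,
                              curve$w_max %||% NA_real_)
  extrapolated <- if (all(is.finite(rng))) {
    w < rng[1] | w > rng[2]
  } else {
    rep(NA, length(w))
  }
  attr(nc, "extrapolated") <- extrapolated
  nc
}

# R^2 robust to zero total variance (exact fits report 1).
rsq <- function(y, res) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    if (sum(res^2) < 1e-12) 1 else 0
  } else {
    1 - sum(res^2) / ss_tot
  }
}

date_treatment_means <- function(obs) {
  obs |>
    dplyr::group_by(.data$n_rate) |>
    dplyr::summarise(w = mean(.data$biomass_w), n_conc = mean(.data$n_conc),
                     .groups = "drop")
}

#' Construct critical nitrogen dilution curves from a trial
#'
#' Runs the full four-step construction for every fertilizer type x cut:
#' (1) per-date ANOVA + LSD classification of rates into nitrogen-limited
#' and non-limited groups, (2) linear regression of N concentration on
#' biomass over the limited treatment means, (3) maximum attainable biomass
#' as the mean of the non-limited treatment means, (4) critical
#' concentration at the intersection — then fits `Nc = a * W^-b` through the
#' per-date critical points. Dates that carry no information (non-significant
#' ANOVA, too few limited treatments, singular regression, non-physical
#' critical concentration) are skipped with a recorded reason, never dropped
#' silently.
#'
#' @param data A [cndc_trial()] or an observation tibble.
#' @param config A [cndc_config()].
#' @return An object of class `cndc_fit` with elements `curves` (tibble, one
#'   row per fitted stratum), `curve_objects` (list of `cndc_curve`),
#'   `critical_points`, `classifications`, `skipped_dates`,
#'   `skipped_strata` (strata with fewer than 3 usable critical points,
#'   reported rather than fitted) and `config`. Errors only when no stratum
#'   at all can be fitted. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' ds <- generate_trial(synthetic_trial_spec(seed = 3))
#' fit <- fit_cndc(ds)
#' tidy(fit)
#' @export
fit_cndc <- function(data, config = cndc_config()) {
  obs <- if (inherits(data, "cndc_trial")) data$observations else
    check_observation_table(data)
  stopifnot(inherits(config, "cndc_config"))

  strata <- dplyr::distinct(obs, .data$fertilizer_type, .data$cut) |>
    dplyr::arrange(.data$fertilizer_type, .data$cut)

  classifications <- list(); points <- list(); skipped <- list()
  curve_objects <- list(); skipped_strata <- list()

  for (i in seq_len(nrow(strata))) {
    ft <- strata$fertilizer_type[i]; ct <- strata$cut[i]
    sub <- dplyr::filter(obs, .data$fertilizer_type == ft, .data$cut == ct)
    stratum_points <- list()
    for (d in sort(unique(sub$date_index))) {
      day <- dplyr::filter(sub, .data$date_index == d)
      cls <- classify_date(day, alpha = config$alpha)
      cls <- dplyr::mutate(cls, fertilizer_type = ft, cut = ct,
                           date_index = d, .before = 1)
      classifications[[length(classifications) + 1]] <- cls

      skip <- function(reason) {
        tibble::tibble(fertilizer_type = ft, cut = ct, date_index = d,
                       reason = reason)
      }
      if (cls$anova_p >= config$alpha) {
        skipped[[length(skipped) + 1]] <-
          skip("no significant biomass response to N rate")
        next
      }
      limited <- cls$limited[[1]]
      if (length(limited) < config$min_limited_points) {
        skipped[[length(skipped) + 1]] <-
          skip(sprintf("fewer than %d nitrogen-limited treatments",
                       config$min_limited_points))
        next
      }
      means <- date_treatment_means(day)
      lim_means <- dplyr::filter(means, .data$n_rate %in% limited)
      reg <- tryCatch(
        limited_regression(lim_means, config$min_limited_points),
        cndc_regression_error = function(e) NULL)
      if (is.null(reg)) {
        skipped[[length(skipped) + 1]] <-
          skip("singular limited-group regression")
        next
      }
      cp <- critical_point(cls, reg, means)
      if (is.null(cp)) {
        skipped[[length(skipped) + 1]] <-
          skip("non-physical critical concentration")
        next
      }
      stratum_points[[length(stratum_points) + 1]] <-
        dplyr::mutate(cp, fertilizer_type = ft, cut = ct, date_index = d,
                      .before = 1)
    }
    stratum_points <- purrr::list_rbind(stratum_points)
    points[[i]] <- stratum_points
    if (nrow(stratum_points) >= 3) {
      curve_objects[[length(curve_objects) + 1]] <- fit_dilution_curve(
        stratum_points, method = config$fit_method,
        fertilizer_type = ft, cut = ct)
    } else {
      skipped_strata[[length(skipped_strata) + 1]] <- tibble::tibble(
        fertilizer_type = ft, cut = ct, n_points = nrow(stratum_points),
        reason = "fewer than 3 usable critical points")
    }
  }
  if (length(curve_objects) == 0) {
    abort("No stratum yielded enough critical points for a dilution-curve fit.",
          class = "cndc_fit_error")
  }

  curves <- purrr::map(curve_objects, function(cv) {
    tibble::tibble(fertilizer_type = cv$fertilizer_type, cut = cv$cut,
                   a = cv$a, b = cv$b, r2 = cv$r2, n_points = cv$n_points,
                   w_min = cv$w_range[1], w_max = cv$w_range[2],
                   method = cv$method)
  }) |> purrr::list_rbind()

  structure(
    list(curves = curves, curve_objects = curve_objects,
         critical_points = purrr::list_rbind(points),
         classifications = purrr::list_rbind(classifications),
         skipped_dates = purrr::list_rbind(skipped),
         skipped_strata = purrr::list_rbind(skipped_strata),
         config = config),
    class = "cndc_fit")
}

#' @export
print.cndc_fit <- function(x, ...) {
  cat("<cndc_fit>\n")
  print(x$curves)
  if (nrow(x$skipped_dates) > 0) {
    cat(sprintf("%d sampling date(s) skipped; see $skipped_dates.\n",
                nrow(x$skipped_dates)))
  }
  if (nrow(x$skipped_strata) > 0) {
    cat(sprintf("%d stratum/strata not fitted; see $skipped_strata.\n",
                nrow(x$skipped_strata)))
  }
  invisible(x)
}

# Look up the curve row for one stratum from a cndc_fit or a curves tibble.
curve_for_stratum <- function(curves, fertilizer_type, cut) {
  tab <- if (inherits(curves, "cndc_fit")) curves$curves else curves
  row <- dplyr::filter(tab, .data$fertilizer_type == !!fertilizer_type,
                       .data$cut == !!cut)
  if (nrow(row) != 1) {
    abort(sprintf("No fitted curve for stratum (%s, cut %s).",
                  fertilizer_type, cut), class = "cndc_missing_curve_error")
  }
  row
}
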