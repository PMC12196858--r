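default_true_params <- function() {
  tibble::tribble(
    ~fertilizer_type, ~cut, ~a,   ~b,
    "urea",           1L,   3.13, 0.35,
    "urea",           2L,   2.21, 0.16,
    "urea",           3L,   1.75, 0.73,
    "cru",            1L,   3.41, 0.20,
    "cru",            2L,   3.15, 0.12,
    "cru",            3L,   2.24, 0.40
  )
}

#' Specification of a synthetic fertilizer trial
#'
#' Describes the generative model behind [generate_trial()]: a two-fertilizer
#' (urea vs controlled-release urea), four-rate, three-cut, replicated trial
#' in which mean biomass rises toward a rate-dependent plateau, plant N
#' concentration dilutes along a per-stratum power law `a * W^-b`, and
#' seasonal yield follows a concave quadratic in the N rate. Default curve
#' parameters and yield quadratics are the values reported for the alfalfa
#' trial the generator emulates; the noise model is multiplicative
#' log-normal so masses and concentrations stay positive.
#'
#' @param n_rates Nitrogen rates tested, kg/ha.
#' @param fertilizer_types Fertilizer type labels.
#' @param cuts Number of harvest cycles per season.
#' @param dates_per_cut Number of weekly samplings within a cut.
#' @param replicates Plots per treatment.
#' @param true_params Tibble with columns `fertilizer_type`, `cut`, `a`, `b`
#'   giving the generating dilution-curve parameters per stratum.
#' @param w0 Initial biomass at the start of a cut, t/ha.
#' @param growth_rate First-order rate at which biomass approaches its
#'   plateau, per sampling interval.
#' @param plateau_base,plateau_gain,plateau_halfsat Michaelis-Menten plateau
#'   in the N rate: `plateau_base + plateau_gain * rate / (rate + halfsat)`,
#'   t/ha.
#' @param deficiency_factor Named numeric, names = N rates; multiplier on
#'   the critical concentration giving each treatment's mean concentration.
#'   Values below 1 emulate N limitation, above 1 luxury uptake.
#' @param noise_cv_biomass,noise_cv_conc Coefficient of variation of the
#'   replicate-level multiplicative noise.
#' @param yield_quadratic Named list per fertilizer type of `c(A, B, C)`
#'   with `A < 0`: mean yield at rate x is `A x^2 + B x + C`, t/ha.
#' @param yield_noise_cv CV of the yield noise.
#' @param year_label Label stamped on the generated yield table.
#' @param seed Master integer seed; per-stratum streams are derived from it
#'   so adding a cut or type does not reshuffle other strata.
#'
#' @return A list of class `cndc_trial_spec`.
#' @examples
#' spec <- synthetic_trial_spec(seed = 42)
#' true_curve(spec, "cru", 1)
#' @export
synthetic_trial_spec <- function(n_rates = c(0, 80, 160, 240),
                                 fertilizer_types = c("urea", "cru"),
                                 cuts = 3L,
                                 dates_per_cut = 5L,
                                 replicates = 3L,
                                 true_params = default_true_params(),
                                 w0 = 1.0,
                                 growth_rate = 0.45,
                                 plateau_base = 5.0,
                                 plateau_gain = 4.0,
                                 plateau_halfsat = 60,
                                 deficiency_factor = c(`0` = 0.75, `80` = 0.90,
                                                       `160` = 1.02,
                                                       `240` = 1.15),
                                 noise_cv_biomass = 0.04,
                                 noise_cv_conc = 0.04,
                                 yield_quadratic = list(
                                   urea = c(A = -1.14e-4, B = 0.04, C = 13.89),
                                   cru  = c(A = -3.09e-4, B = 0.09, C = 14.11)),
                                 yield_noise_cv = 0.03,
                                 year_label = "season_1",
                                 seed = 1L) {
  if (any(c(noise_cv_biomass, noise_cv_conc, yield_noise_cv) < 0)) {
    abort("Noise CVs must be nonnegative.", class = "cndc_spec_error")
  }
  if (any(n_rates < 0)) {
    abort("N rates must be nonnegative.", class = "cndc_spec_error")
  }
  for (ft in names(yield_quadratic)) {
    if (yield_quadratic[[ft]][["A"]] >= 0) {
      abort(sprintf("yield_quadratic for %s must have A < 0 (concave response).",
                    ft), class = "cndc_spec_error")
    }
  }
  if (is.null(names(deficiency_factor)) ||
      !all(as.character(n_rates) %in% names(deficiency_factor))) {
    abort("`deficiency_factor` must be named by every N rate.",
          class = "cndc_spec_error")
  }
  if (any(deficiency_factor <= 0 | deficiency_factor > 1.5)) {
    abort("`deficiency_factor` values must lie in (0, 1.5].",
          class = "cndc_spec_error")
  }
  need <- tidyr::expand_grid(fertilizer_type = fertilizer_types,
                             cut = seq_len(cuts))
  have <- dplyr::semi_join(need, true_params,
                           by = c("fertilizer_type", "cut"))
  if (nrow(have) < nrow(need)) {
    abort("`true_params` must cover every fertilizer_type x cut stratum.",
          class = "cndc_spec_error")
  }
  structure(
    list(n_rates = n_rates, fertilizer_types = fertilizer_types,
         cuts = as.integer(cuts), dates_per_cut = as.integer(dates_per_cut),
         replicates = as.integer(replicates), true_params = true_params,
         w0 = w0, growth_rate = growth_rate, plateau_base = plateau_base,
         plateau_gain = plateau_gain, plateau_halfsat = plateau_halfsat,
         deficiency_factor = deficiency_factor,
         noise_cv_biomass = noise_cv_biomass, noise_cv_conc = noise_cv_conc,
         yield_quadratic = yield_quadratic, yield_noise_cv = yield_noise_cv,
         year_label = year_label, seed = as.integer(seed)),
    class = "cndc_trial_spec"
  )
}

#' True dilution-curve parameters of a synthetic stratum
#'
#' @param spec A [synthetic_trial_spec()].
#' @param fertilizer_type,cut Stratum key.
#' @return Named numeric `c(a, b)`.
#' @export
true_curve <- function(spec, fertilizer_type, cut) {
  stopifnot(inherits(spec, "cndc_trial_spec"))
  row <- dplyr::filter(spec$true_params,
                       .data$fertilizer_type == !!fertilizer_type,
                       .data$cut == !!cut)
  if (nrow(row) != 1) {
    abort(sprintf("No true curve for stratum (%s, cut %s).",
                  fertilizer_type, cut), class = "cndc_spec_error")
  }
  c(a = row$a, b = row$b)
}

#' Analytic optimum of a synthetic yield response
#'
#' Vertex of the generating quadratic: rate `-B / (2A)`, yield
#' `C - B^2 / (4A)`.
#'
#' @param spec A [synthetic_trial_spec()].
#' @param fertilizer_type Fertilizer type key.
#' @return Named numeric `c(opt_rate, max_yield)`.
#' @export
true_optimum <- function(spec, fertilizer_type) {
  stopifnot(inherits(spec, "cndc_trial_spec"))
  q <- spec$yield_quadratic[[fertilizer_type]]
  if (is.null(q)) {
    abort(sprintf("No yield quadratic for fertilizer type %s.",
                  fertilizer_type), class = "cndc_spec_error")
  }
  optimum(q[["A"]], q[["B"]], q[["C"]])
}

# Mean biomass after `t` sampling intervals: first-order approach from w0
# toward the rate-dependent plateau.
mean_biomass <- function(spec, rate, t) {
  plateau <- spec$plateau_base +
    spec$plateau_gain * rate / (rate + spec$plateau_halfsat)
  plateau - (plateau - spec$w0) * exp(-spec$growth_rate * t)
}

# Multiplicative log-normal factor with unit mean and the given CV.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

stratum_seed <- function(master, type_index, cut, what) {
  (abs(master) + 7919L * type_index + 104729L * cut + 15485863L * what) %%
    2147483629L + 1L
}

#' Generate a synthetic trial dataset
#'
#' Draws a full replicated trial from the generative model described in
#' [synthetic_trial_spec()]. Deterministic for a given spec (including its
#' seed); random streams are derived per stratum so altering one stratum's
#' design does not reshuffle others.
#'
#' @param spec A [synthetic_trial_spec()].
#' @return A [cndc_trial()] with observations and yields; `metadata` records
#'   the seed and the generating parameters.
#' @examples
#' ds <- generate_trial(synthetic_trial_spec(seed = 7))
#' ds
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "cndc_trial_spec"))
  grid <- tidyr::expand_grid(
    type_index = seq_along(spec$fertilizer_types),
    cut = seq_len(spec$cuts))
  obs <- purrr::pmap(grid, function(type_index, cut) {
    ft <- spec$fertilizer_types[type_index]
    ab <- true_curve(spec, ft, cut)
    set.seed(stratum_seed(spec$seed, type_index, cut, 1L))
    rows <- tidyr::expand_grid(date_index = seq_len(spec$dates_per_cut),
                               n_rate = spec$n_rates,
                               replicate = seq_len(spec$replicates))
    mu_w <- mean_biomass(spec, rows$n_rate, rows$date_index)
    w <- mu_w * lognormal_factor(nrow(rows), spec$noise_cv_biomass)
    fac <- unname(spec$deficiency_factor[as.character(rows$n_rate)])
    # concentration noise is independent of biomass noise: the mean
    # concentration follows the treatment's mean trajectory
    mu_conc <- fac * ab[["a"]] * mu_w^(-ab[["b"]])
    conc <- mu_conc * lognormal_factor(nrow(rows), spec$noise_cv_conc)
    tibble::tibble(fertilizer_type = ft, n_rate = rows$n_rate, cut = cut,
                   date_index = rows$date_index, replicate = rows$replicate,
                   biomass_w = w, n_conc = conc)
  }) |> purrr::list_rbind()

  yields <- purrr::imap(
    setNames(seq_along(spec$fertilizer_types), spec$fertilizer_types),
    function(type_index, ft) {
      q <- spec$yield_quadratic[[ft]]
      if (is.null(q)) return(NULL)
      set.seed(stratum_seed(spec$seed, type_index, 0L, 2L))
      rows <- tidyr::expand_grid(n_rate = spec$n_rates,
                                 replicate = seq_len(spec$replicates))
      mu <- q[["A"]] * rows$n_rate^2 + q[["B"]] * rows$n_rate + q[["C"]]
      tibble::tibble(fertilizer_type = ft, n_rate = rows$n_rate,
                     year_label = spec$year_label, replicate = rows$replicate,
                     yield_t_ha = mu * lognormal_factor(nrow(rows),
                                                        spec$yield_noise_cv))
    }) |> purrr::list_rbind()
  if (nrow(yields) == 0) yields <- NULL

  cndc_trial(obs, yields,
             metadata = list(generator = "cndc::generate_trial",
                             seed = spec$seed, spec = spec))
}
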