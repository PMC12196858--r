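# Small fixture builders shared across test files.

# Replicate table for one sampling date: group means plus a fixed
# within-group jitter pattern, balanced with 3 replicates.
date_fixture <- function(means, rates = c(0, 80, 160, 240),
                         jitter = c(-0.1, 0, 0.1)) {
  tidyr::expand_grid(n_rate = rates, replicate = seq_along(jitter)) |>
    dplyr::mutate(
      fertilizer_type = "urea", cut = 1L, date_index = 1L,
      biomass_w = means[match(n_rate, rates)] + jitter[replicate],
      n_conc = 3)
}

# Independent LSD oracle: straight from the textbook formula.
lsd_oracle <- function(obs, alpha = 0.05) {
  groups <- split(obs$biomass_w, obs$n_rate)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_within <- length(obs$biomass_w) - length(groups)
  r <- length(groups) / sum(1 / lengths(groups))
  qt(1 - alpha / 2, df_within) * sqrt(2 * (ss_within / df_within) / r)
}

noiseless_spec <- function(seed = 1, ...) {
  synthetic_trial_spec(seed = seed, noise_cv_biomass = 0, noise_cv_conc = 0,
                       yield_noise_cv = 0, ...)
}
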