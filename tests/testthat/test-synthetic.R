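test_that("generation is deterministic given the spec seed", {
  spec <- synthetic_trial_spec(seed = 99)
  a <- generate_trial(spec)
  b <- generate_trial(spec)
  expect_identical(a$observations, b$observations)
  expect_identical(a$yields, b$yields)
})

test_that("the noiseless limit reproduces the generating dilution law exactly", {
  spec <- noiseless_spec(seed = 1)
  ds <- generate_trial(spec)
  obs <- ds$observations

  # every replicate equals its treatment mean
  per_treatment <- obs |>
    dplyr::group_by(fertilizer_type, cut, date_index, n_rate) |>
    dplyr::summarise(spread_w = diff(range(biomass_w)),
                     spread_c = diff(range(n_conc)), .groups = "drop")
  expect_true(all(per_treatment$spread_w == 0))
  expect_true(all(per_treatment$spread_c == 0))

  # concentration sits exactly at factor * a * W^-b; with factor 1 and
  # W = 1 t/ha that is the parameter a itself
  for (ft in c("urea", "cru")) for (ct in 1:3) {
    sub <- dplyr::filter(obs, fertilizer_type == ft, cut == ct)
    ab <- true_curve(spec, ft, ct)
    fac <- spec$deficiency_factor[as.character(sub$n_rate)]
    expect_equal(sub$n_conc, unname(fac) * ab[["a"]] * sub$biomass_w^(-ab[["b"]]),
                 tolerance = 1e-12)
  }
  one <- synthetic_trial_spec(deficiency_factor = c(`0` = 1, `80` = 1,
                                                    `160` = 1, `240` = 1))
  expect_equal(1 * true_curve(one, "cru", 1)[["a"]] * 1^(-0.20), 3.41)
})

test_that("mean biomass increases with N rate and plateaus at the top rates", {
  ds <- generate_trial(noiseless_spec(seed = 1))
  means <- ds$observations |>
    dplyr::filter(fertilizer_type == "urea", cut == 1) |>
    dplyr::group_by(date_index, n_rate) |>
    dplyr::summarise(w = mean(biomass_w), .groups = "drop")
  for (d in unique(means$date_index)) {
    m <- means[means$date_index == d, ]
    m <- m[order(m$n_rate), ]
    expect_true(all(diff(m$w) > 0))
    top2 <- utils::tail(m$w, 2)
    expect_lt(diff(top2) / max(top2), 0.05)
  }
})

test_that("true parameter lookups return the generating values", {
  spec <- synthetic_trial_spec()
  expect_equal(true_curve(spec, "cru", 1), c(a = 3.41, b = 0.20))
  expect_equal(true_curve(spec, "urea", 3), c(a = 1.75, b = 0.73))
  expect_error(true_curve(spec, "urea", 9), class = "cndc_spec_error")

  override <- spec$true_params
  override$a[override$fertilizer_type == "cru" & override$cut == 1] <- 9
  spec2 <- synthetic_trial_spec(true_params = override)
  expect_equal(true_curve(spec2, "cru", 1)[["a"]], 9)
})

test_that("true_optimum returns the analytic vertex of the yield quadratic", {
  spec <- synthetic_trial_spec()
  expect_equal(round(unname(true_optimum(spec, "urea")), 2), c(175.44, 17.40))
  expect_equal(round(unname(true_optimum(spec, "cru")), 2), c(145.63, 20.66))
  spec3 <- synthetic_trial_spec(
    yield_quadratic = list(urea = c(A = -1, B = 0, C = 5)))
  expect_equal(unname(true_optimum(spec3, "urea")), c(0, 5))
  expect_error(
    synthetic_trial_spec(yield_quadratic = list(urea = c(A = 1, B = 0, C = 5))),
    class = "cndc_spec_error")
})

test_that("invalid generator settings are rejected", {
  expect_error(synthetic_trial_spec(noise_cv_conc = -0.1),
               class = "cndc_spec_error")
  expect_error(synthetic_trial_spec(deficiency_factor = c(`0` = 0.75)),
               class = "cndc_spec_error")
  expect_error(synthetic_trial_spec(n_rates = c(-5, 80)),
               class = "cndc_spec_error")
})

test_that("sample means converge to the stated treatment means", {
  spec <- synthetic_trial_spec(seed = 4, replicates = 200)
  ds <- generate_trial(spec)
  sub <- ds$observations |>
    dplyr::filter(fertilizer_type == "cru", cut == 1) |>
    dplyr::group_by(date_index, n_rate) |>
    dplyr::summarise(w = mean(biomass_w), conc = mean(n_conc),
                     .groups = "drop")
  truth <- generate_trial(noiseless_spec(seed = 4)) $observations |>
    dplyr::filter(fertilizer_type == "cru", cut == 1, replicate == 1)
  joined <- dplyr::inner_join(sub, truth, by = c("date_index", "n_rate"))
  expect_true(all(abs(joined$w / joined$biomass_w - 1) < 0.02))
  expect_true(all(abs(joined$conc / joined$n_conc - 1) < 0.02))
})

test_that("generated concentrations are positive and dilute as biomass grows", {
  ds <- generate_trial(synthetic_trial_spec(seed = 12))
  expect_true(all(ds$observations$n_conc > 0))
  trend <- generate_trial(noiseless_spec(seed = 12)) $observations |>
    dplyr::filter(replicate == 1) |>
    dplyr::arrange(fertilizer_type, cut, n_rate, date_index) |>
    dplyr::group_by(fertilizer_type, cut, n_rate) |>
    dplyr::summarise(monotone = all(diff(n_conc) < 0), .groups = "drop")
  expect_true(all(trend$monotone))
})
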