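test_that("classification matches a hand-computed LSD split", {
  obs <- date_fixture(means = c(2, 3, 4, 4))
  cls <- classify_date(obs, alpha = 0.05)
  lsd <- lsd_oracle(obs)
  expect_equal(cls$lsd, lsd)
  expect_lt(cls$anova_p, 0.05)
  expect_equal(cls$limited[[1]], c(0, 80))
  expect_equal(cls$non_limited[[1]], c(160, 240))
})

test_that("a non-significant ANOVA declares every rate non-limited", {
  obs <- date_fixture(means = c(3, 3, 3, 3))
  cls <- classify_date(obs)
  expect_gte(cls$anova_p, 0.05)
  expect_equal(cls$non_limited[[1]], c(0, 80, 160, 240))
  expect_length(cls$limited[[1]], 0)
})

test_that("fully separated means leave only the top rate non-limited", {
  obs <- date_fixture(means = c(2, 4, 6, 8))
  cls <- classify_date(obs)
  # brute-force check: every pairwise gap exceeds the LSD
  means <- tapply(obs$biomass_w, obs$n_rate, mean)
  expect_true(all(dist(means) > cls$lsd))
  expect_equal(cls$non_limited[[1]], 240)
  expect_equal(cls$limited[[1]], c(0, 80, 160))
})

test_that("replicate structure is enforced, harmonic mean used when unbalanced", {
  single <- date_fixture(means = c(2, 3, 4, 4))
  single <- single[!(single$n_rate == 0 & single$replicate > 1), ]
  expect_error(classify_date(single), class = "cndc_classification_error")

  unbal <- date_fixture(means = c(2, 3, 4, 4))
  unbal <- unbal[!(unbal$n_rate == 0 & unbal$replicate == 3), ]
  expect_warning(cls <- classify_date(unbal), "harmonic")
  expect_equal(cls$lsd, lsd_oracle(unbal))
})

test_that("the limited-group regression reproduces exact lines", {
  two <- data.frame(w = c(2, 4), n_conc = c(3, 2))
  reg <- limited_regression(two)
  expect_equal(reg$slope, -0.5)
  expect_equal(reg$intercept, 4)
  expect_equal(reg$r2, 1)

  coll <- data.frame(w = c(1, 3, 6))
  coll$n_conc <- 5 - 0.3 * coll$w
  reg <- limited_regression(coll)
  expect_equal(reg$slope, -0.3)
  expect_equal(reg$intercept, 5)

  flat <- data.frame(w = c(2, 3, 4), n_conc = c(3, 3, 3))
  reg <- limited_regression(flat)
  expect_equal(reg$slope, 0)
  expect_equal(reg$intercept, 3)

  expect_error(limited_regression(two[1, ]), class = "cndc_regression_error")
  expect_error(
    limited_regression(data.frame(w = c(2, 2), n_conc = c(1, 2))),
    class = "cndc_regression_error")
})

test_that("critical points sit on the regression line at the plateau biomass", {
  cls <- tibble::tibble(non_limited = list(c(160, 240)))
  reg <- list(slope = -0.5, intercept = 4, r2 = 1)
  means <- data.frame(n_rate = c(0, 80, 160, 240), w = c(2, 3, 4.0, 4.2))
  cp <- critical_point(cls, reg, means)
  expect_equal(cp$w_max, 4.1)
  expect_equal(cp$nc, -0.5 * 4.1 + 4)

  # non-physical critical concentration is rejected, not reported
  means$w[means$n_rate >= 160] <- 10
  expect_null(critical_point(cls, reg, means))
})

test_that("the power-law fit inverts noiseless data exactly", {
  w <- c(2, 4, 6, 8)
  pts <- data.frame(w_max = w, nc = 3.41 * w^(-0.20))
  cv <- fit_dilution_curve(pts)
  expect_equal(cv$a, 3.41, tolerance = 1e-10)
  expect_equal(cv$b, 0.20, tolerance = 1e-10)
  expect_equal(cv$r2, 1)
  expect_error(fit_dilution_curve(pts[1:2, ]), class = "cndc_fit_error")
})

test_that("the power-law fit tolerates moderate noise", {
  set.seed(101)
  w <- c(1.5, 2.5, 4, 5.5, 7, 8.5)
  nc <- 3.0 * w^(-0.3) * exp(rnorm(6, 0, sqrt(log(1 + 0.05^2))))
  cv <- fit_dilution_curve(data.frame(w_max = w, nc = nc))
  # frozen from an initial run of this generator; bands: a +/-10%, b +/-0.1
  expect_equal(cv$a, 2.919362, tolerance = 1e-6)
  expect_equal(cv$b, 0.273411, tolerance = 1e-6)
  expect_lt(abs(cv$a / 3.0 - 1), 0.10)
  expect_lt(abs(cv$b - 0.3), 0.10)
})

test_that("log-log and nls fits agree on noiseless inputs", {
  w <- c(2, 3.5, 5, 6.5, 8)
  pts <- data.frame(w_max = w, nc = 2.24 * w^(-0.40))
  log_fit <- fit_dilution_curve(pts, method = "loglog_ols")
  nls_fit <- fit_dilution_curve(pts, method = "nls")
  expect_lt(abs(nls_fit$a / log_fit$a - 1), 0.01)
  expect_lt(abs(nls_fit$b - log_fit$b), 0.02)
})

test_that("critical concentration predictions follow the power law", {
  expect_equal(as.numeric(predict_nc(list(a = 3.13, b = 0.35), 1)), 3.13)
  expect_equal(as.numeric(predict_nc(list(a = 3.41, b = 0.20), 8)), 2.2498,
               tolerance = 1e-4)
  expect_error(predict_nc(list(a = 3, b = 0.2), 0),
               class = "cndc_domain_error")
  expect_error(predict_nc(list(a = 3, b = 0.2), -2),
               class = "cndc_domain_error")

  curve <- list(a = 3, b = 0.2, w_range = c(2, 6))
  out <- predict_nc(curve, c(1, 3, 9))
  expect_equal(attr(out, "extrapolated"), c(TRUE, FALSE, TRUE))
})

test_that("predicted concentration is strictly decreasing in biomass", {
  set.seed(7)
  for (i in 1:50) {
    curve <- list(a = runif(1, 1, 5), b = runif(1, 0.05, 1))
    w <- sort(runif(2, 0.5, 12))
    nc <- as.numeric(predict_nc(curve, w))
    expect_gt(nc[1], nc[2])
  }
})

test_that("noiseless plateau data classify coherently and recover the truth", {
  spec <- noiseless_spec(seed = 1)
  ds <- generate_trial(spec)
  fit <- fit_cndc(ds)

  # the highest rate is always non-limited
  top <- max(spec$n_rates)
  expect_true(all(vapply(fit$classifications$non_limited,
                         function(x) top %in% x, logical(1))))

  # recovered parameters sit close to the generating values; the residual
  # offset is the structural bias of the intersection construction
  for (i in seq_len(nrow(fit$curves))) {
    row <- fit$curves[i, ]
    tr <- true_curve(spec, row$fertilizer_type, row$cut)
    expect_lt(abs(row$a / tr[["a"]] - 1), 0.10)
    expect_lt(abs(row$b - tr[["b"]]), 0.05)
  }
})

test_that("uninformative dates are skipped with recorded reasons", {
  ds <- generate_trial(synthetic_trial_spec(seed = 1))
  fit <- fit_cndc(ds)
  expect_true(all(c("fertilizer_type", "cut", "date_index", "reason") %in%
                    names(fit$skipped_dates)))
  # every stratum-date is either a critical point or a recorded skip
  n_dates <- nrow(dplyr::distinct(ds$observations, fertilizer_type, cut,
                                  date_index))
  expect_equal(nrow(fit$critical_points) + nrow(fit$skipped_dates), n_dates)
})
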