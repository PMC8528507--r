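test_that("proportional step follows its closed form and clipping", {
  cfg <- tracker_config(target_mep = 0.2, max_step = 2, gain = 2)
  # on target: unchanged
  expect_equal(proportional_step(50, 0.2, cfg), 50)
  # 10-fold-or-worse miss below target: full step upward
  expect_equal(proportional_step(50, 0.02, cfg), 52)
  # 2-fold above target: step of -2*log10(2)
  expect_equal(proportional_step(50, 0.4, cfg), 50 - 2 * log10(2))
  # clipped to the deliverable range
  expect_equal(proportional_step(99.5, 0.002, cfg), 100)
  expect_equal(proportional_step(0.5, 20, cfg), 0)
  # zero responses are treated as the noise floor (step upward)
  expect_gt(proportional_step(50, 0, cfg), 50)
})

test_that("estimate validity requires a hit within tolerance or a bracket", {
  cfg <- tracker_config(target_mep = 0.2, tracking_error_tol = 0.2)
  expect_true(is_valid_estimate(NA, 0.2, cfg))            # exact hit
  expect_true(is_valid_estimate(0.1, 0.3, cfg))           # bracketed
  expect_false(is_valid_estimate(0.3, 0.26, cfg))         # 1.3x, same side
  expect_true(is_valid_estimate(0.3, 0.24, cfg))          # within 1.2x
  expect_false(is_valid_estimate(NA, 0.3, cfg))
  # tolerance limits: huge tolerance accepts everything on scale,
  # tiny tolerance accepts only exact hits or brackets
  loose <- tracker_config(tracking_error_tol = 0.999)
  expect_true(is_valid_estimate(0.21, 0.25, loose))
  tight <- tracker_config(tracking_error_tol = 1e-9)
  expect_false(is_valid_estimate(0.21, 0.25, tight))
  expect_true(is_valid_estimate(0.1, 0.4, tight))
})

test_that("regression threshold recovers exact and symmetric cases", {
  # exact line through (50 %MSO, 0.2 mV), slope 0.05
  est <- regression_threshold(line_trials(c(46, 48, 50, 52, 54)))
  expect_true(est$valid)
  expect_equal(est$value, 50)
  expect_equal(est$beta, 0.05)

  # two-point log-midpoint symmetry
  tr <- data.frame(ts_intensity = c(48, 52), mep_mv = c(0.1, 0.4),
                   gated = FALSE)
  expect_equal(regression_threshold(tr)$value, 50)
})

test_that("window exclusion drops off-scale points and matches an OLS oracle", {
  set.seed(21)
  x <- seq(44, 56, length.out = 20)
  y <- 0.05 * (x - 50) + log10(0.2) + rnorm(20, 0, 0.03)
  clean <- data.frame(ts_intensity = x, mep_mv = 10^y, gated = FALSE)
  with_outlier <- rbind(clean,
                        data.frame(ts_intensity = 70, mep_mv = 3.0,
                                   gated = FALSE))
  e1 <- regression_threshold(clean)
  e2 <- regression_threshold(with_outlier)
  expect_equal(e1$value, e2$value)
  expect_equal(e2$n_excluded, 1)

  # within 0.5 %MSO of a direct normal-equations fit on the clean points
  beta_o <- cov(x, y) / var(x)
  alpha_o <- mean(y) - beta_o * mean(x)
  expect_lt(abs(e1$value - (log10(0.2) - alpha_o) / beta_o), 0.5)
})

test_that("regression threshold handles gated, degenerate and invalid input", {
  tr <- line_trials(c(46, 48, 50, 52))
  tr$gated[1] <- TRUE
  est <- regression_threshold(tr)
  expect_equal(est$value, 50)       # gated point excluded, line unchanged
  expect_equal(est$n_excluded, 1)

  # fewer than 2 usable points
  expect_false(regression_threshold(tr[1:2, ])$valid)
  # single intensity: singular design
  one <- data.frame(ts_intensity = rep(50, 5), mep_mv = rep(0.2, 5),
                    gated = FALSE)
  expect_false(regression_threshold(one)$valid)
  # negative slope is not a recruitment curve
  dec <- data.frame(ts_intensity = c(48, 52), mep_mv = c(0.4, 0.1),
                    gated = FALSE)
  expect_false(regression_threshold(dec)$valid)
})

test_that("regression threshold is order-invariant and shift-equivariant", {
  set.seed(22)
  x <- 45 + sample(0:10)
  tr <- line_trials(x)
  tr$mep_mv <- tr$mep_mv * 10^rnorm(length(x), 0, 0.1)
  e <- regression_threshold(tr)
  e_perm <- regression_threshold(tr[sample(nrow(tr)), ])
  expect_equal(e$value, e_perm$value)

  shifted <- tr
  shifted$ts_intensity <- shifted$ts_intensity + 7
  expect_equal(regression_threshold(shifted)$value, e$value + 7)
})

test_that("noiseless tracking converges to the true threshold", {
  m <- noiseless_model(theta = 55)
  trk <- track_threshold(m, tracker_config(), start_intensity = 62)
  expect_true(trk$estimate$valid)
  expect_lt(abs(trk$estimate$value - 55), 0.5)
  expect_lte(nrow(trk$trials), 100)
})

test_that("tracking is shift-equivariant across subjects", {
  set.seed(23)
  m55 <- excitability_model(theta_true = 55, slope_b = 0.05, sigma_log = 0.2)
  m60 <- excitability_model(theta_true = 60, slope_b = 0.05, sigma_log = 0.2)
  set.seed(99)
  e55 <- track_threshold(m55, tracker_config(), 62)$estimate$value
  set.seed(99)
  e60 <- track_threshold(m60, tracker_config(), 67)$estimate$value
  expect_lt(abs((e60 - e55) - 5), 0.5)
})

test_that("noisy tracking is approximately unbiased", {
  m <- excitability_model(theta_true = 55, slope_b = 0.05, sigma_log = 0.2)
  set.seed(24)
  est <- replicate(80, track_threshold(m, tracker_config(), 62)$estimate$value)
  expect_lt(mean(is.na(est)), 0.1)
  expect_lt(abs(mean(est, na.rm = TRUE) - 55), 1.5)
})
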