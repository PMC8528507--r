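test_that("schedules have exact condition counts and seeded determinism", {
  cfg <- protocol_config()
  set.seed(31)
  s <- build_schedule(cfg)
  expect_equal(nrow(s), 120)
  expect_equal(sum(s$condition == "2.5"), 10)
  expect_equal(sum(startsWith(s$condition, "control")), 30)
  # every cycle is one permutation of the 12 conditions
  for (cy in 1:10)
    expect_setequal(s$condition[s$cycle == cy],
                    c(as.character(cfg$isis), paste0("control", 1:3)))
  set.seed(77); s1 <- build_schedule(cfg)
  set.seed(77); s2 <- build_schedule(cfg)
  expect_identical(s1, s2)
})

test_that("pseudorandomisation places conditions uniformly within cycles", {
  cfg <- protocol_config()
  set.seed(32)
  hits <- matrix(0, 12, 12)   # condition x within-cycle position
  conds <- c(as.character(cfg$isis), paste0("control", 1:3))
  for (r in 1:1000) {
    s <- build_schedule(cfg)
    hits <- hits + table(factor(match(s$condition, conds), 1:12),
                         factor(s$position, 1:12))
  }
  freq <- hits / (1000 * 10)
  expect_true(all(abs(freq - 1 / 12) < 0.02))
})

test_that("prestimulus gate discards only peaks strictly exceeding 0.015 mV", {
  expect_true(gate_prestimulus(0.010))
  expect_false(gate_prestimulus(0.016))
  expect_true(gate_prestimulus(0.015))   # boundary kept
  expect_true(gate_prestimulus(0))
  expect_false(gate_prestimulus(0.2, protocol_config()))
})

test_that("SICI formulas follow their definitions and sign conventions", {
  expect_equal(compute_t_sici(55, 55), 0)
  expect_equal(compute_t_sici(60.5, 55), 10)
  expect_equal(compute_t_sici(49.5, 55), -10)     # facilitation
  expect_error(compute_t_sici(50, 0), "rmt")

  expect_equal(compute_a_sici(c(0.2, 0.2), c(0.2, 0.2)), 100)
  expect_equal(compute_a_sici(c(0.1, 0.4), c(0.2, 0.2)), 100)  # geometric
  expect_equal(compute_a_sici(c(0.1, 0.1), c(0.2, 0.2)), 50)
  expect_true(is.na(compute_a_sici(numeric(0), c(0.2))))
})

test_that("noiseless T-SICI recovers the imposed inhibition profile", {
  m <- noiseless_model(theta = 55, b = 0.05)
  set.seed(33)
  r <- run_t_sici(m, 55)
  expect_s3_class(r, "examination_result")
  expect_true(r$valid)
  for (isi in names(m$inhibition_profile))
    expect_lt(abs(r$sici[isi] - m$inhibition_profile[isi]), 1.0)
  # band averages are arithmetic means of member ISIs
  expect_equal(r$band_1_3.5,
               mean(r$sici[c("1", "1.5", "2", "2.5", "3", "3.5")]))
  expect_equal(r$band_1_7, mean(r$sici))
  # trial-log conservation: 90 paired + 30 control
  expect_equal(sum(!startsWith(r$trials$condition, "control")), 90)
  expect_equal(sum(startsWith(r$trials$condition, "control")), 30)
})

test_that("a null subject yields T-SICI of zero at every ISI", {
  prof <- default_inhibition_profile() * 0
  m <- noiseless_model(theta = 55, b = 0.065, profile = prof)
  set.seed(34)
  r <- run_t_sici(m, 55)
  expect_true(all(abs(r$sici) < 1.0))
})

test_that("A-SICI matches the recruitment-model closed form", {
  prof <- default_inhibition_profile() * 0
  m0 <- noiseless_model(theta = 55, b = 0.05, profile = prof)
  set.seed(35)
  r0 <- run_a_sici(m0, 55, 55 + log10(5) / 0.05)
  expect_true(all(r0$sici == 100))
  expect_equal(r0$band_1_7, 100)

  # delta_abs = 4 %MSO at 2.5 ms -> 100 * 10^(-0.05*4) = 63.1
  prof["2.5"] <- 4 / 55 * 100
  m <- noiseless_model(theta = 55, b = 0.05, profile = prof)
  set.seed(36)
  r <- run_a_sici(m, 55, 55 + log10(5) / 0.05)
  expect_equal(unname(r$sici["2.5"]), 100 * 10^(-0.2), tolerance = 1e-10)
  # intensities never change during an A-SICI examination
  expect_equal(length(unique(r$trials$ts_intensity)), 1)
  expect_equal(sum(!startsWith(r$trials$condition, "control")), 90)
})

test_that("noisy A-SICI concentrates on the closed form in geometric mean", {
  prof <- default_inhibition_profile()
  m <- excitability_model(theta_true = 55, slope_b = 0.05, sigma_log = 0.2,
                          inhibition_profile = prof)
  closed <- 100 * 10^(-0.05 * prof["2.5"] / 100 * 55)
  set.seed(37)
  vals <- replicate(30, run_a_sici(m, 55, 55 + log10(5) / 0.05)$sici["2.5"])
  gm <- exp(mean(log(vals)))
  expect_lt(abs(log(gm / closed)), log(1.05))
})

test_that("gated sweeps are discarded and redelivered, keeping counts fixed", {
  m <- excitability_model(theta_true = 55, slope_b = 0.05, sigma_log = 0.1,
                          contamination_rate = 0.15,
                          contamination_amp_mv = 0.5)
  set.seed(38)
  r <- run_a_sici(m, 55, 69)
  expect_gt(r$gated_count, 0)
  ok <- r$trials[!r$trials$gated, ]
  expect_equal(sum(!startsWith(ok$condition, "control")), 90)
  expect_equal(sum(startsWith(ok$condition, "control")), 30)
  expect_equal(r$gated_count, sum(r$trials$gated))
})

test_that("noiseless subjects tie the two protocols through the recruitment slope", {
  m <- noiseless_model(theta = 55, b = 0.05)
  set.seed(39)
  rt <- run_t_sici(m, 55)
  ra <- run_a_sici(m, 55, 55 + log10(5) / 0.05)
  # log10(A-SICI/100) = -slope_b * (T-SICI/100) * theta across ISIs
  x <- as.numeric(rt$sici) / 100 * 55
  y <- log10(as.numeric(ra$sici) / 100)
  fit <- lm(y ~ x)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_lt(abs(coef(fit)[2] - (-0.05)), 0.005)
})
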