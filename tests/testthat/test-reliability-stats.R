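test_that("within-subject SD matches closed forms and the one-way ANOVA oracle", {
  x <- matrix(c(1, 2, 3, 4, 2, 1, 4, 3), 4, 2)   # paired diffs -1, 1, -1, 1
  expect_equal(within_subject_sd(x), sqrt(4 / 8))
  expect_equal(within_subject_sd(matrix(c(1, 2, 3, 1, 2, 3), 3, 2)), 0)

  set.seed(41)
  for (i in 1:5) {
    m <- matrix(rnorm(18), 6, 3)
    expect_equal(within_subject_sd(m), oracle_sigma_w(m), tolerance = 1e-10)
  }
  expect_error(within_subject_sd(matrix(1:4, 4, 1)), "repeats")
})

test_that("coefficient of repeatability reproduces its closed forms", {
  x <- matrix(c(1, 2, 3, 4, 2, 1, 4, 3), 4, 2)   # sigma_w = 1/sqrt(2)
  cr <- coefficient_of_repeatability(x)
  expect_equal(cr$cr, 1.96)
  expect_lt(cr$ci[1], cr$cr); expect_gt(cr$ci[2], cr$cr)
  expect_equal(coefficient_of_repeatability(
    matrix(c(5, 6, 5, 6), 2, 2))$cr, 0)

  # log10 duplicates 10-fold apart: sigma_w = 1/sqrt(2) log10 units,
  # back-transformed CR = 10^1.96 = 91.2-fold
  lg <- measurement_matrix(cbind(c(0, 1, 2), c(1, 2, 3)), scale = "log10")
  cr <- coefficient_of_repeatability(lg)
  expect_equal(cr$cr_ratio, 10^1.96)
  expect_equal(round(cr$cr_ratio, 1), 91.2)
})

test_that("CR is scale-equivariant", {
  set.seed(42)
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(coefficient_of_repeatability(3.7 * x)$cr,
               3.7 * coefficient_of_repeatability(x)$cr)
})

test_that("ICC(2,1) matches hand-computed and definitional oracles", {
  x <- matrix(c(1, 3, 5, 2, 4, 6), 3, 2)
  ic <- icc_2_1(x)
  expect_equal(ic$icc, 8 / 9)             # MSR=8, MSC=1.5, MSE=0
  expect_equal(ic$band, "good")

  # identical column copies of distinct rows: perfect agreement
  y <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(icc_2_1(y)$icc, 1)

  set.seed(43)
  for (i in 1:10) {
    m <- matrix(rnorm(20), 10, 2) + rnorm(10)
    expect_equal(icc_2_1(m)$icc, oracle_icc21(m), tolerance = 1e-10)
    expect_equal(icc_2_1(m)$icc, oracle_icc21_pairs(m[, 1], m[, 2]),
                 tolerance = 1e-10)
  }

  # shift invariance
  m <- matrix(rnorm(24), 8, 3) + rnorm(8)
  expect_equal(icc_2_1(m + 100)$icc, icc_2_1(m)$icc, tolerance = 1e-10)

  # zero total variance is undefined, with a diagnostic
  expect_message(res <- icc_2_1(matrix(5, 4, 2)), "undefined")
  expect_true(is.na(res$icc))
})

test_that("ICC confidence interval brackets the estimate sensibly", {
  set.seed(44)
  m <- matrix(rnorm(36, sd = 0.5), 12, 3) + 2 * rnorm(12)
  ic <- icc_2_1(m)
  expect_true(ic$ci[1] < ic$icc && ic$icc < ic$ci[2])
  expect_true(ic$ci[2] <= 1)
})

test_that("added noise decreases ICC in expectation", {
  set.seed(45)
  base <- matrix(rnorm(30, sd = 0.2), 15, 2) + 3 * rnorm(15)
  icc_lo <- median(replicate(40, icc_2_1(base +
    matrix(rnorm(30, sd = 0.1), 15, 2))$icc))
  icc_hi <- median(replicate(40, icc_2_1(base +
    matrix(rnorm(30, sd = 2.0), 15, 2))$icc))
  expect_gt(icc_lo, icc_hi)
})

test_that("ICC qualitative bands use the stated boundaries", {
  expect_equal(classify_icc(0.45), "poor")
  expect_equal(classify_icc(0.50), "moderate")
  expect_equal(classify_icc(0.749), "moderate")
  expect_equal(classify_icc(0.75), "good")
  expect_equal(classify_icc(0.82), "good")
  expect_equal(classify_icc(0.90), "good")     # upper bound inclusive
  expect_equal(classify_icc(0.901), "excellent")
  expect_error(classify_icc(1.2), "exceed")
})

test_that("repeated-measures ANOVA matches the textbook oracle", {
  # two levels: sphericity trivially holds
  set.seed(46)
  x2 <- matrix(rnorm(20), 10, 2)
  a2 <- rm_anova(x2)
  expect_equal(a2$mauchly_W, 1)
  expect_equal(a2$epsilon, 1)

  # identical columns: no condition effect
  xc <- matrix(rnorm(12), 12, 1)[, c(1, 1, 1)] +
    matrix(rnorm(36, sd = 0.5), 12, 3)
  xc[, 2] <- xc[, 1]; xc[, 3] <- xc[, 1]
  expect_equal(rm_anova(xc)$F, 0)

  set.seed(47)
  for (i in 1:8) {
    m <- matrix(rnorm(48), 12, 4) + rnorm(12)
    mine <- rm_anova(m)
    orc <- oracle_rmanova(m)
    expect_equal(mine$F, orc$F, tolerance = 1e-8)
    expect_equal(mine$p_uncorrected, orc$p, tolerance = 1e-8)
    expect_equal(mine$epsilon, orc$epsilon, tolerance = 1e-8)
    # base R's second-order Box term uses a slightly different
    # coefficient; agreement to ~1e-3 is the expected match
    expect_equal(mine$mauchly_p, orc$mauchly_p, tolerance = 2e-3)
    expect_true(mine$epsilon >= 1 / (ncol(m) - 1) && mine$epsilon <= 1)
  }
  expect_error(rm_anova(matrix(1:5, 5, 1)), "repeated")
})

test_that("pairwise post hoc tests carry Bonferroni-adjusted p values", {
  set.seed(48)
  m <- matrix(rnorm(30), 10, 3)
  m[, 3] <- m[, 3] + 2
  ph <- pairwise_bonferroni(m)
  expect_equal(nrow(ph), 3)
  raw13 <- t.test(m[, 1], m[, 3], paired = TRUE)$p.value
  expect_equal(ph$p_adjusted[ph$i == 1 & ph$j == 3], min(1, 3 * raw13))
})

test_that("Bland-Altman agreement follows its closed forms", {
  a <- c(1, 2, 3); b <- a
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, c(0, 0))

  ba <- bland_altman(c(2, 1), c(1, 2))      # diffs 1, -1
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, c(-1, 1) * 1.96 * sqrt(2))

  # constant 2-fold ratio on the log scale: ratio 2, zero-width limits
  x <- log10(c(2, 4, 8)); y <- log10(c(1, 2, 4))
  ba <- bland_altman(x, y, scale = "log10")
  expect_equal(ba$bias_ratio, 2)
  expect_equal(ba$loa_ratio, c(2, 2))

  # antisymmetry: swapping the methods negates the bias
  set.seed(49)
  u <- rnorm(10); v <- rnorm(10)
  expect_equal(bland_altman(u, v)$bias, -bland_altman(v, u)$bias)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("one-sample condition test handles exact nulls and closed forms", {
  r <- one_sample_condition_test(c(5, 5, 5), 5)
  expect_equal(r$t, 0); expect_equal(r$p, 1)

  r <- one_sample_condition_test(c(1, 2, 3), 0)
  expect_equal(r$t, sqrt(12), tolerance = 1e-6)   # 2 / (1/sqrt(3)) = 3.464
  expect_equal(r$df, 2)
  expect_error(one_sample_condition_test(1, 0), "n >= 2")
})

test_that("inter-method regression recovers lines and correlations", {
  mr <- method_regression(c(0, 1, 2), c(0, 1, 2), log10_x = FALSE)
  expect_equal(mr$slope, 1); expect_equal(mr$intercept, 0)
  expect_equal(mr$r, 1)

  # log10 transform applied to the amplitude-method predictor
  a <- c(100, 50, 25, 12.5)
  t_ <- c(0, 5, 10, 15)
  mr <- method_regression(t_, a)
  expect_equal(mr$r2, 1, tolerance = 1e-12)
  expect_equal(mr$slope, 5 / log10(0.5))

  set.seed(50)
  x1 <- rnorm(5000)
  x2 <- 0.8 * x1 + sqrt(1 - 0.8^2) * rnorm(5000)
  mr <- method_regression(x1, x2, log10_x = FALSE)
  expect_lt(abs(mr$r - 0.8), 0.02)
  expect_true(mr$ci_r[1] < 0.8 && 0.8 < mr$ci_r[2])
  expect_error(method_regression(1:4, rep(1, 4), log10_x = FALSE),
               "variance")
})

test_that("measurement matrices apply listwise deletion and carry scale", {
  v <- rbind(c(1, 2), c(NA, 3), c(4, 5))
  expect_message(m <- measurement_matrix(v), "listwise")
  expect_equal(nrow(m), 2)
  lg <- measurement_matrix(rbind(c(1, 2), c(3, 4)), scale = "log10")
  expect_equal(attr(lg, "scale"), "log10")
})
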