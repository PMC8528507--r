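# Independent definitional oracles used to cross-check the reliability
# statistics.  These deliberately take different computational routes from
# the package (stats::aov, stats::mauchly.test, double-centered covariance,
# raw definitional sums).

# One-way (subjects) ANOVA residual mean square via stats::aov.
oracle_sigma_w <- function(x) {
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(seq_len(nrow(x)), ncol(x))))
  ms <- summary(stats::aov(y ~ subj, data = df))[[1]]["Residuals", "Mean Sq"]
  sqrt(ms)
}

# ICC(2,1) from definitional sums of squares (no shared code with the
# package implementation).
oracle_icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  ssr <- sum((rowMeans(x) - g)^2) * k
  ssc <- sum((colMeans(x) - g)^2) * n
  sse <- sum((x - outer(rowMeans(x), colMeans(x), "+") + g)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# ICC(2,1) for two repeats from the paired difference/sum decomposition.
oracle_icc21_pairs <- function(a, b) {
  n <- length(a)
  d <- a - b
  msr <- stats::var(a + b) / 2
  mse <- stats::var(d) / 2
  msc <- n * mean(d)^2 / 2
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}

# Repeated-measures ANOVA oracle: F and p from stats::aov with an Error
# stratum, Greenhouse-Geisser epsilon from the double-centered covariance
# matrix, Mauchly p from stats::mauchly.test on the multivariate fit.
oracle_rmanova <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(seq_len(n), k)),
                   cond = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ cond + Error(subj / cond),
                            data = df))[["Error: subj:cond"]][[1]]
  s <- stats::cov(x)
  d <- sweep(sweep(s, 1, rowMeans(s)), 2, colMeans(s)) + mean(s)
  eps <- sum(diag(d))^2 / ((k - 1) * sum(d^2))
  mau <- stats::mauchly.test(stats::lm(x ~ 1), X = ~1,
                             idata = data.frame(cond = factor(seq_len(k))))
  list(F = tab["cond", "F value"], p = tab["cond", "Pr(>F)"],
       epsilon = eps, mauchly_p = mau$p.value)
}

# Noise-free trials exactly on a recruitment line through (theta, target).
line_trials <- function(intensities, theta = 50, beta = 0.05,
                        target = 0.2) {
  data.frame(ts_intensity = intensities,
             mep_mv = target * 10^(beta * (intensities - theta)),
             gated = FALSE)
}

# A small noiseless reference subject used across protocol tests.
noiseless_model <- function(theta = 55, b = 0.05,
                            profile = default_inhibition_profile()) {
  excitability_model(theta_true = theta, slope_b = b, sigma_log = 0,
                     inhibition_profile = profile)
}
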