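#' Subjects-by-repeats measurement matrix
#'
#' The unit of all reliability statistics: one row per subject, one column
#' per repeated measurement of a single parameter.  Parameters with
#' log-normal measurement distributions (amplitude-ratio SICI) should be
#' stored on the log10 scale (`scale = "log10"`), in which case
#' repeatability and agreement statistics are additionally back-transformed
#' to fold-change ratios.  Rows containing missing values are dropped
#' (listwise deletion) with a message.
#'
#' @param values Numeric matrix or data frame, subjects x repeats.
#' @param parameter Parameter name (e.g. `"T-SICI_2.5ms"`).
#' @param scale `"linear"` or `"log10"`.
#' @param units Measurement units (e.g. `"%RMT"`, `"%MSO"`).
#' @return An object of class `measurement_matrix` (a matrix with
#'   attributes).
#' @export
measurement_matrix <- function(values, parameter = "parameter",
                               scale = c("linear", "log10"), units = "") {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  drop <- apply(values, 1, anyNA)
  if (any(drop)) {
    message(sprintf("measurement_matrix: dropping %d subject(s) with missing values (listwise deletion)",
                    sum(drop)))
    values <- values[!drop, , drop = FALSE]
  }
  structure(values, parameter = parameter, scale = scale, units = units,
            class = c("measurement_matrix", "matrix"))
}

mm_values <- function(m) {
  if (inherits(m, "measurement_matrix")) unclass(m) else as.matrix(m)
}

mm_scale <- function(m) {
  s <- attr(m, "scale")
  if (is.null(s)) "linear" else s
}

# Two-way (subjects x repeats) mean squares underlying sigma_w, ICC and the
# repeated-measures ANOVA.
mean_squares <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  list(n = n, k = k,
       msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)),
       msw = (sst - ssr) / (n * (k - 1)))
}

#' Within-subject standard deviation
#'
#' The square root of the within-subject mean square from a one-way
#' (subjects) ANOVA.  With exactly two repeats this reduces to
#' `sqrt(sum(d^2) / (2 n))` where `d` are the paired differences.
#'
#' @param m A [measurement_matrix()] or numeric matrix (subjects x repeats,
#'   >= 2 repeats).
#' @return The within-subject SD, in the units of the measurements.
#' @export
within_subject_sd <- function(m) {
  x <- mm_values(m)
  if (ncol(x) < 2) stop("need >= 2 repeats", call. = FALSE)
  sqrt(mean_squares(x)$msw)
}

#' Coefficient of repeatability
#'
#' `CR = 1.96 * sqrt(2) * sigma_w`: the bound that the absolute difference
#' between any two future replicate measurements on the same subject will
#' not exceed on 95\% of occasions.  The 95\% CI follows from the exact
#' chi-square distribution of `sigma_w^2` with `n (k - 1)` degrees of
#' freedom.  For log10-scale matrices the back-transformed value `10^CR`
#' (and its CI) is also reported; it is a dimensionless fold-change bound
#' on the *relative* difference between two future measurements.
#'
#' @param m A [measurement_matrix()] or numeric matrix (subjects x repeats).
#' @param conf_level Confidence level for the CI.
#' @return List with `cr`, `ci` (length 2), `sigma_w`, and, on the log10
#'   scale, `cr_ratio` and `ci_ratio`.
#' @export
coefficient_of_repeatability <- function(m, conf_level = 0.95) {
  x <- mm_values(m)
  sw <- within_subject_sd(x)
  df <- nrow(x) * (ncol(x) - 1)
  a <- (1 - conf_level) / 2
  ci_sw <- sw * sqrt(df / stats::qchisq(c(1 - a, a), df))
  out <- list(cr = 1.96 * sqrt(2) * sw, ci = 1.96 * sqrt(2) * ci_sw,
              sigma_w = sw)
  if (mm_scale(m) == "log10") {
    out$cr_ratio <- 10^out$cr
    out$ci_ratio <- 10^out$ci
  }
  out
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, single-rating, absolute-agreement intraclass
#' correlation:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`,
#' where MSR, MSC and MSE are the subject, repeat and error mean squares.
#' The confidence interval is the standard F-based interval for this form.
#'
#' @param m A [measurement_matrix()] or numeric matrix (n >= 2 subjects,
#'   k >= 2 repeats).
#' @param conf_level Confidence level.
#' @return List with `icc`, `ci`, `band` (qualitative label from
#'   [classify_icc()]) and the mean squares.  `icc` is `NA` (with a
#'   diagnostic message) when the matrix has zero total variance.
#' @export
icc_2_1 <- function(m, conf_level = 0.95) {
  x <- mm_values(m)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 repeats", call. = FALSE)
  if (stats::var(as.vector(x)) == 0) {
    message("icc_2_1: zero total variance; ICC undefined")
    return(list(icc = NA_real_, ci = c(NA_real_, NA_real_),
                band = NA_character_))
  }
  ms <- mean_squares(x)
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))

  # F-based CI (two-way random, absolute agreement, single rating)
  a <- (1 - conf_level) / 2
  if (ms$mse == 0 && ms$msc == ms$mse) {
    ci <- c(icc, icc)
  } else {
    fj <- if (ms$mse > 0) ms$msc / ms$mse else 1e12
    vn <- (k - 1) * (n - 1) *
      (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    fl <- stats::qf(1 - a, n - 1, v)
    fu <- stats::qf(1 - a, v, n - 1)
    lower <- n * (ms$msr - fl * ms$mse) /
      (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    upper <- n * (fu * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
    ci <- c(lower, upper)
  }
  list(icc = icc, ci = ci, band = classify_icc(icc),
       msr = ms$msr, msc = ms$msc, mse = ms$mse)
}

#' Qualitative reliability band of an ICC
#'
#' poor (< 0.50), moderate (0.50--0.749), good (0.75--0.90, upper bound
#' inclusive), excellent (> 0.90).
#'
#' @param icc ICC value(s), each <= 1.
#' @return Character vector of band labels.
#' @export
classify_icc <- function(icc) {
  if (any(icc > 1, na.rm = TRUE)) stop("ICC cannot exceed 1", call. = FALSE)
  ifelse(is.na(icc), NA_character_,
         ifelse(icc < 0.50, "poor",
                ifelse(icc < 0.75, "moderate",
                       ifelse(icc <= 0.90, "good", "excellent"))))
}

#' Repeated-measures ANOVA with sphericity handling
#'
#' One within-subject factor (the repeated examination, `k` levels) on `n`
#' subjects.  Mauchly's test of sphericity is computed from the
#' orthonormal-contrast-projected covariance matrix; if it rejects at
#' `sphericity_alpha`, the Greenhouse--Geisser epsilon rescales the degrees
#' of freedom for the reported p value.  With `k = 2` sphericity holds
#' trivially (W = 1, epsilon = 1).
#'
#' @param m A [measurement_matrix()] or numeric matrix, no missing cells.
#' @param sphericity_alpha Significance level of Mauchly's test that
#'   triggers the correction.
#' @return List with `F`, `df1`, `df2` (uncorrected), `p` (corrected if
#'   triggered), `p_uncorrected`, `epsilon` (Greenhouse--Geisser),
#'   `mauchly_W`, `mauchly_p`, `gg_applied`.
#' @export
rm_anova <- function(m, sphericity_alpha = 0.05) {
  x <- mm_values(m)
  n <- nrow(x); k <- ncol(x)
  if (k < 2) stop("need >= 2 repeated measurements", call. = FALSE)
  ms <- mean_squares(x)
  f <- if (ms$mse > 0) ms$msc / ms$mse else if (ms$msc > 0) Inf else 0
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)

  if (k == 2) {
    w <- 1; mauchly_p <- 1; eps <- 1
  } else {
    s <- stats::cov(x)
    cm <- contrast_matrix(k)
    t_mat <- cm %*% s %*% t(cm)
    lambda <- eigen(t_mat, symmetric = TRUE, only.values = TRUE)$values
    lambda <- pmax(lambda, 0)
    if (sum(lambda) <= 1e-12 * max(sum(abs(diag(s))), .Machine$double.eps)) {
      # no within-subject variability at all: sphericity is vacuous
      return(list(F = f, df1 = df1, df2 = df2,
                  p = stats::pf(f, df1, df2, lower.tail = FALSE),
                  p_uncorrected = stats::pf(f, df1, df2, lower.tail = FALSE),
                  epsilon = 1, mauchly_W = 1, mauchly_p = 1,
                  gg_applied = FALSE))
    }
    eps <- sum(lambda)^2 / (df1 * sum(lambda^2))
    eps <- min(max(eps, 1 / df1), 1)
    if (any(lambda <= 1e-10 * max(lambda))) {
      # rank-deficient (e.g. fewer subjects than repeats): Mauchly's test
      # is unavailable; apply the correction at the conservative bound
      warning("singular within-subject covariance; epsilon at lower bound")
      w <- NA_real_; mauchly_p <- NA_real_
      eps <- 1 / df1
    } else {
      w <- prod(lambda) / (mean(lambda))^df1
      # Box chi-square approximation with second-order correction
      pp <- df1; nf <- n - 1
      dfm <- pp * (pp + 1) / 2 - 1
      rho <- 1 - (2 * pp^2 + pp + 2) / (6 * pp * nf)
      w2 <- (pp + 2) * (pp - 1) * (pp - 2) *
        (2 * pp^3 + 6 * pp^2 + 3 * pp + 2) / (288 * pp^2 * nf^2 * rho^2)
      z <- -nf * rho * log(w)
      mauchly_p <- stats::pchisq(z, dfm, lower.tail = FALSE) +
        w2 * (stats::pchisq(z, dfm + 4, lower.tail = FALSE) -
                stats::pchisq(z, dfm, lower.tail = FALSE))
    }
  }
  p_unc <- stats::pf(f, df1, df2, lower.tail = FALSE)
  gg <- is.na(mauchly_p) || mauchly_p < sphericity_alpha
  p <- if (gg) stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
       else p_unc
  list(F = f, df1 = df1, df2 = df2, p = p, p_uncorrected = p_unc,
       epsilon = eps, mauchly_W = w, mauchly_p = mauchly_p, gg_applied = gg)
}

# Orthonormal polynomial-style contrasts, (k-1) x k with rows orthonormal
# and orthogonal to the unit vector.
contrast_matrix <- function(k) {
  cm <- stats::contr.helmert(k)  # k x (k-1)
  cm <- t(cm)
  sw <- sqrt(rowSums(cm^2))
  cm / sw
}

#' Pairwise post hoc comparisons with Bonferroni correction
#'
#' Paired t tests between all column pairs of a measurement matrix, with
#' Bonferroni-adjusted p values; the follow-up applied when the
#' repeated-measures omnibus test is significant.
#'
#' @param m A [measurement_matrix()] or numeric matrix.
#' @return Data frame with columns `i`, `j`, `t`, `df`, `p_adjusted`.
#' @export
pairwise_bonferroni <- function(m) {
  x <- mm_values(m)
  k <- ncol(x)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    tt <- stats::t.test(x[, ij[1]], x[, ij[2]], paired = TRUE)
    c(i = ij[1], j = ij[2], t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value)
  })
  out <- as.data.frame(t(res))
  out$p_adjusted <- pmin(out$p * ncol(pairs), 1)
  out$p <- NULL
  out
}

#' Bland--Altman agreement analysis
#'
#' Bias (mean difference) and 95\% limits of agreement
#' `bias +/- 1.96 * SD(differences)` for paired measurements.  On the log10
#' scale all three quantities are additionally back-transformed to ratios:
#' the geometric-mean ratio and fold-change limits.
#'
#' @param a,b Paired measurement vectors of equal length >= 2 (already
#'   log10-transformed when `scale = "log10"`).
#' @param scale `"linear"` or `"log10"`.
#' @return List with `bias`, `loa` (length 2), `sd_diff`, and on the log10
#'   scale `bias_ratio`, `loa_ratio`.
#' @export
bland_altman <- function(a, b, scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length",
                                   call. = FALSE)
  if (length(a) < 2) stop("need >= 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sd_d
  out <- list(bias = bias, loa = loa, sd_diff = sd_d)
  if (scale == "log10") {
    out$bias_ratio <- 10^bias
    out$loa_ratio <- 10^loa
  }
  out
}

#' One-sample t test against a control condition
#'
#' Two-sided test of whether a set of SICI values differs from its null
#' (0 \%RMT for threshold-tracking SICI; log10(100) for log10-transformed
#' amplitude SICI).
#'
#' @param values Numeric vector, n >= 2.
#' @param null_value The null hypothesis value.
#' @return List with `t`, `df`, `p`, `mean`.
#' @export
one_sample_condition_test <- function(values, null_value = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need n >= 2", call. = FALSE)
  if (stats::sd(values) == 0) {
    # degenerate: zero spread; on the null the statistic is 0, off it infinite
    on_null <- mean(values) == null_value
    return(list(t = if (on_null) 0 else sign(mean(values) - null_value) * Inf,
                df = length(values) - 1,
                p = if (on_null) 1 else 0,
                mean = mean(values)))
  }
  tt <- stats::t.test(values, mu = null_value)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = mean(values))
}

#' Inter-method regression of threshold-tracking on amplitude SICI
#'
#' Ordinary least squares of per-subject mean T-SICI on (by default) the
#' log10 of per-subject mean A-SICI, with the Pearson correlation and its
#' Fisher-z confidence interval.
#'
#' @param t_sici_means Per-subject T-SICI means (response).
#' @param a_sici_means Per-subject A-SICI means (predictor); log10 is taken
#'   internally unless `log10_x = FALSE`.
#' @param log10_x Transform the predictor to log10 first?
#' @param conf_level Confidence level for the correlation CI.
#' @return List with `slope`, `intercept`, `r`, `r2`, `ci_r`, `n`.
#' @export
method_regression <- function(t_sici_means, a_sici_means, log10_x = TRUE,
                              conf_level = 0.95) {
  ok <- !is.na(t_sici_means) & !is.na(a_sici_means)
  y <- t_sici_means[ok]
  x <- if (log10_x) log10(a_sici_means[ok]) else a_sici_means[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in predictor", call. = FALSE)
  fit <- wls_fit(x, y, rep(1, n))
  r <- stats::cor(x, y)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
  list(slope = fit$beta, intercept = fit$alpha, r = r, r2 = r^2,
       ci_r = tanh(c(z - zc, z + zc)), n = n)
}
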