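#' Define one virtual subject's corticospinal excitability model
#'
#' A virtual subject is characterised by a log-linear MEP recruitment curve:
#' over the interval 0.02--2 mV the log10 MEP amplitude grows linearly with
#' stimulus intensity, and the curve passes exactly through 0.2 mV at the
#' resting motor threshold `theta_true`.  Outside that interval the curve
#' saturates smoothly towards a baseline noise floor and a ceiling amplitude.
#' Trial-to-trial variability is multiplicative (log-normal), conditioning
#' stimuli act as a pure leftward/rightward shift of the curve along the
#' intensity axis, and each examination may carry an additive threshold drift.
#'
#' @param theta_true True resting motor threshold (\%MSO): the intensity at
#'   which the noise-free MEP equals 0.2 mV.
#' @param slope_b Recruitment slope, log10(mV) per \%MSO.  Must be positive.
#' @param sigma_log Trial-to-trial SD of log10 MEP amplitude.
#' @param mep_floor Baseline noise amplitude (mV) that responses saturate to
#'   far below threshold.
#' @param mep_ceiling Saturation amplitude (mV) far above threshold.
#' @param inhibition_profile Named numeric vector mapping ISI (ms, as names)
#'   to the true conditioned-threshold shift, expressed as \% of
#'   `theta_true`; positive values are inhibition, negative facilitation.
#' @param session_drift_sd SD (\%MSO) of the additive per-examination shift
#'   of `theta_true`.
#' @param contamination_rate Per-sweep probability of a prestimulus EMG
#'   contamination event.
#' @param contamination_amp_mv Mean of the exponential distribution from
#'   which contamination peak amplitudes (mV) are drawn.
#'
#' @return An object of class `excitability_model`.
#' @seealso [sample_cohort()], [generate_mep()]
#' @export
#' @examples
#' m <- excitability_model(theta_true = 55, slope_b = 0.065, sigma_log = 0)
#' generate_mep(m, intensity = 55)  # exactly 0.2 mV
excitability_model <- function(theta_true = 55,
                               slope_b = 0.065,
                               sigma_log = 0.2,
                               mep_floor = 0.005,
                               mep_ceiling = 5.0,
                               inhibition_profile = default_inhibition_profile(),
                               session_drift_sd = 0,
                               contamination_rate = 0,
                               contamination_amp_mv = 0.05) {
  if (!is.numeric(slope_b) || slope_b <= 0)
    stop("'slope_b' must be > 0", call. = FALSE)
  if (sigma_log < 0) stop("'sigma_log' must be >= 0", call. = FALSE)
  if (!(mep_floor < 0.02 && 2 <= mep_ceiling))
    stop("need mep_floor < 0.02 and mep_ceiling >= 2", call. = FALSE)
  if (theta_true < 0 || theta_true > 100)
    stop("'theta_true' must be in [0, 100] %MSO", call. = FALSE)
  if (session_drift_sd < 0 || contamination_rate < 0 || contamination_rate > 1)
    stop("invalid drift/contamination parameters", call. = FALSE)
  if (is.null(names(inhibition_profile)))
    stop("'inhibition_profile' must be a named vector (names = ISI in ms)",
         call. = FALSE)
  structure(
    list(theta_true = theta_true, slope_b = slope_b, sigma_log = sigma_log,
         mep_floor = mep_floor, mep_ceiling = mep_ceiling,
         inhibition_profile = inhibition_profile,
         session_drift_sd = session_drift_sd,
         contamination_rate = contamination_rate,
         contamination_amp_mv = contamination_amp_mv),
    class = "excitability_model")
}

#' Default true inhibition profile (percent of RMT) across ISIs
#'
#' Threshold shifts at the nine protocol ISIs, anchored at the group mean
#' T-SICI values reported for 1, 2.5 and 3 ms; remaining ISIs are free
#' defaults chosen to give the canonical SICI shape: strong inhibition at
#' 1 ms, a second peak near 2.5 ms, decay through 3.5--5 ms and mild
#' facilitation at 7 ms.
#'
#' @return Named numeric vector (names = ISI in ms, values = \% of RMT).
#' @export
default_inhibition_profile <- function() {
  c("1" = 10.3, "1.5" = 8.0, "2" = 7.0, "2.5" = 7.5, "3" = 5.5,
    "3.5" = 4.0, "4" = 2.0, "5" = 0.0, "7" = -4.0)
}

#' Cohort-level simulation parameters
#'
#' Describes the population from which virtual subjects are drawn.  Defaults
#' emulate a healthy adult cohort: RMT ~ Normal(55.2, 8.4) \%MSO (truncated
#' to 20--95 so that a test stimulus at 120\% RMT stays deliverable),
#' recruitment slopes around 0.065 log10(mV)/\%MSO (which places TS_1mV near
#' 120\% of RMT), and a shared mean inhibition profile with a between-subject
#' additive spread.
#'
#' @param n_subjects Number of virtual subjects (>= 1).
#' @param rmt_mean,rmt_sd Between-subject mean and SD of the true RMT (\%MSO).
#' @param slope_mean,slope_sd Between-subject distribution of the recruitment
#'   slope (truncated below at 0.02).
#' @param sigma_log_mean Trial-to-trial log10-MEP SD given to every subject.
#' @param inhibition_profile_mean Named vector, mean threshold shift per ISI
#'   (\% of RMT).
#' @param inhibition_profile_sd_between SD (\% of RMT) of a per-subject
#'   additive offset applied to the whole profile.
#' @param session_drift_sd Per-examination threshold drift SD (\%MSO).
#' @param contamination_rate Per-sweep prestimulus contamination probability.
#' @param contamination_amp_mv Mean contamination peak amplitude (mV).
#' @param seed Optional integer; when given, [sample_cohort()] seeds the RNG
#'   with it so the cohort is reproducible in isolation.
#'
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 18,
                          rmt_mean = 55.2,
                          rmt_sd = 8.4,
                          slope_mean = 0.065,
                          slope_sd = 0.01,
                          sigma_log_mean = 0.2,
                          inhibition_profile_mean = default_inhibition_profile(),
                          inhibition_profile_sd_between = 6,
                          session_drift_sd = 2,
                          contamination_rate = 0.02,
                          contamination_amp_mv = 0.05,
                          seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("'n_subjects' must be >= 1", call. = FALSE)
  sds <- c(rmt_sd, slope_sd, inhibition_profile_sd_between, session_drift_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), rmt_mean = rmt_mean,
         rmt_sd = rmt_sd, slope_mean = slope_mean, slope_sd = slope_sd,
         sigma_log_mean = sigma_log_mean,
         inhibition_profile_mean = inhibition_profile_mean,
         inhibition_profile_sd_between = inhibition_profile_sd_between,
         session_drift_sd = session_drift_sd,
         contamination_rate = contamination_rate,
         contamination_amp_mv = contamination_amp_mv,
         seed = seed),
    class = "cohort_params")
}

# Truncated-normal draws by rejection; bounds are far enough out that the
# acceptance rate is essentially 1 for all realistic parameter choices.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Draw a cohort of virtual subjects
#'
#' Thresholds are drawn from Normal(`rmt_mean`, `rmt_sd`) truncated to
#' 20--95 \%MSO; slopes from a normal truncated below; each subject's
#' inhibition profile is the cohort mean profile plus one subject-level
#' offset shared across ISIs (so a strongly inhibited subject is strongly
#' inhibited at every ISI, and a subject with a sufficiently negative offset
#' shows facilitation throughout).
#'
#' @param params A [cohort_params()] object.
#' @return List of [excitability_model()] objects, one per subject.
#' @export
#' @examples
#' cohort <- sample_cohort(cohort_params(n_subjects = 3, seed = 1))
#' vapply(cohort, function(m) m$theta_true, numeric(1))
sample_cohort <- function(params) {
  if (!inherits(params, "cohort_params"))
    stop("'params' must be a cohort_params object", call. = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_subjects
  theta <- rtruncnorm(n, params$rmt_mean, params$rmt_sd, 20, 95)
  slope <- rtruncnorm(n, params$slope_mean, params$slope_sd, 0.02, Inf)
  offset <- stats::rnorm(n, 0, params$inhibition_profile_sd_between)
  lapply(seq_len(n), function(i) {
    excitability_model(
      theta_true = theta[i], slope_b = slope[i],
      sigma_log = params$sigma_log_mean,
      inhibition_profile = params$inhibition_profile_mean + offset[i],
      session_drift_sd = params$session_drift_sd,
      contamination_rate = params$contamination_rate,
      contamination_amp_mv = params$contamination_amp_mv)
  })
}

# Smooth saturation in log10 space: identity (exactly linear) inside the
# 0.02-2 mV window, C1 exponential-approach tails towards the floor and
# ceiling outside it.  Exact linearity inside the window is required so that
# threshold regression and the closed-form conditioned/control MEP ratio hold
# without approximation error.
soft_clamp_log10 <- function(y, floor_log, ceiling_log,
                             lin_lo = log10(0.02), lin_hi = log10(2)) {
  hi <- y > lin_hi
  lo <- y < lin_lo
  if (any(hi)) {
    span <- ceiling_log - lin_hi
    y[hi] <- ceiling_log - span * exp(-(y[hi] - lin_hi) / span)
  }
  if (any(lo)) {
    span <- lin_lo - floor_log
    y[lo] <- floor_log + span * exp((y[lo] - lin_lo) / span)
  }
  y
}

#' Generate stochastic MEP amplitudes from a virtual subject
#'
#' The noise-free core of the response is
#' `log10(MEP) = log10(0.2) + slope_b * (intensity - delta_shift - theta_true
#' - drift)`, smoothly saturated towards `mep_floor` and `mep_ceiling`
#' outside the 0.02--2 mV window, after which log-normal trial-to-trial
#' noise with SD `sigma_log` is added in log10 space.  A conditioning
#' stimulus enters only through `delta_shift`, a rightward shift of the
#' recruitment curve along the intensity axis (its value in \%MSO equals the
#' true conditioned-threshold elevation).
#'
#' Uses the session R random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param model An [excitability_model()].
#' @param intensity Stimulus intensity(ies), \%MSO, each in \[0, 100\].
#' @param delta_shift Conditioning-induced threshold shift (\%MSO, absolute).
#' @param drift Additive per-examination threshold drift (\%MSO).
#' @return Numeric vector of MEP amplitudes (mV), same length as `intensity`.
#' @export
generate_mep <- function(model, intensity, delta_shift = 0, drift = 0) {
  if (any(intensity < 0 | intensity > 100))
    stop("'intensity' must be within [0, 100] %MSO", call. = FALSE)
  y <- log10(0.2) +
    model$slope_b * (intensity - delta_shift - model$theta_true - drift)
  y <- soft_clamp_log10(y, log10(model$mep_floor), log10(model$mep_ceiling))
  if (model$sigma_log > 0)
    y <- y + stats::rnorm(length(y), 0, model$sigma_log)
  10^y
}

#' Sample a prestimulus EMG contamination event
#'
#' With probability `contamination_rate` the sweep carries a spontaneous
#' prestimulus EMG peak whose amplitude is drawn from an exponential
#' distribution with mean `contamination_amp_mv`; otherwise the prestimulus
#' window is clean (peak 0 mV).  Whether a contaminated sweep is actually
#' discarded is decided downstream by [gate_prestimulus()] against the
#' 0.015 mV gate.
#'
#' @param model An [excitability_model()].
#' @return List with elements `contaminated` (logical) and `peak_mv` (mV).
#' @export
sample_prestim_event <- function(model) {
  if (model$contamination_rate > 0 &&
      stats::runif(1) < model$contamination_rate) {
    list(contaminated = TRUE,
         peak_mv = stats::rexp(1, rate = 1 / model$contamination_amp_mv))
  } else {
    list(contaminated = FALSE, peak_mv = 0)
  }
}

#' @export
print.excitability_model <- function(x, ...) {
  cat("Virtual subject excitability model\n")
  cat(sprintf("  theta_true : %.1f %%MSO (MEP = 0.2 mV)\n", x$theta_true))
  cat(sprintf("  slope_b    : %.4f log10(mV)/%%MSO\n", x$slope_b))
  cat(sprintf("  sigma_log  : %.3f log10 units\n", x$sigma_log))
  cat(sprintf("  drift SD   : %.2f %%MSO; contamination %.1f%%\n",
              x$session_drift_sd, 100 * x$contamination_rate))
  cat("  inhibition profile (% of RMT):\n")
  print(round(x$inhibition_profile, 2))
  invisible(x)
}
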