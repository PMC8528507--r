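#' Configuration of the proportional threshold tracker
#'
#' @param target_mep Target MEP amplitude (mV): 0.2 for resting-motor-
#'   threshold tracking, 1.0 for TS_1mV.
#' @param max_step Maximum intensity step per trial (\%MSO); 2 for the
#'   initial RMT/TS tracking, 1 for in-protocol channels.
#' @param gain Proportional gain, \%MSO per log10 unit of MEP error.  The
#'   default (equal to `max_step`) delivers the full step only for a
#'   10-fold-or-worse miss, so the approach to threshold is smooth.
#' @param valid_estimates_required Number of valid estimates at which the
#'   tracked threshold is deemed stable (6).
#' @param tracking_error_tol Allowed fractional tracking error on the log
#'   scale: a trial "hits" the target if
#'   `|log10(MEP/target)| <= log10(1 + tol)` (default tol 0.2).
#' @param regression_window Amplitude window (mV) of the linear part of the
#'   recruitment curve; responses outside it are excluded from threshold
#'   regression.
#' @param max_trials Safety cap on delivered trials per tracked threshold.
#'
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(target_mep = 0.2,
                           max_step = 2,
                           gain = max_step,
                           valid_estimates_required = 6,
                           tracking_error_tol = 0.2,
                           regression_window = c(0.02, 2.0),
                           max_trials = 100) {
  if (max_step <= 0) stop("'max_step' must be > 0", call. = FALSE)
  if (tracking_error_tol <= 0 || tracking_error_tol >= 1)
    stop("'tracking_error_tol' must be in (0, 1)", call. = FALSE)
  if (target_mep <= 0) stop("'target_mep' must be > 0", call. = FALSE)
  structure(
    list(target_mep = target_mep, max_step = max_step, gain = gain,
         valid_estimates_required = as.integer(valid_estimates_required),
         tracking_error_tol = tracking_error_tol,
         regression_window = regression_window,
         max_trials = as.integer(max_trials)),
    class = "tracker_config")
}

#' Proportional tracking step
#'
#' The next stimulus intensity is decreased, increased or left unchanged
#' according to whether the observed MEP was above, below or on target:
#' `step = clip(-gain * log10(observed/target), +/- max_step)`, and the
#' result is clipped to the deliverable range \[0, 100\] \%MSO.
#'
#' @param current Current stimulus intensity (\%MSO).
#' @param observed_mep Observed MEP amplitude (mV); non-positive values are
#'   replaced by `mep_floor` before taking logs.
#' @param cfg A [tracker_config()].
#' @param mep_floor Substitute amplitude for zero responses (mV).
#' @return Next stimulus intensity (\%MSO).
#' @export
proportional_step <- function(current, observed_mep, cfg,
                              mep_floor = 0.005) {
  observed_mep <- ifelse(observed_mep <= 0, mep_floor, observed_mep)
  step <- -cfg$gain * log10(observed_mep / cfg$target_mep)
  step <- pmin(pmax(step, -cfg$max_step), cfg$max_step)
  pmin(pmax(current + step, 0), 100)
}

#' Validity of a single threshold estimate
#'
#' An estimate is valid if the current MEP hit the target line within the
#' allowed tracking error on the log scale, or if the previous and current
#' MEPs bracketed it (landed on opposite sides).
#'
#' @param prev_mep Previous MEP (mV), or `NA` if there is none yet.
#' @param cur_mep Current MEP (mV).
#' @param cfg A [tracker_config()].
#' @return Logical flag.
#' @export
is_valid_estimate <- function(prev_mep, cur_mep, cfg) {
  lc <- log10(cur_mep / cfg$target_mep)
  if (abs(lc) <= log10(1 + cfg$tracking_error_tol)) return(TRUE)
  if (is.na(prev_mep)) return(FALSE)
  lp <- log10(prev_mep / cfg$target_mep)
  sign(lp) != sign(lc)
}

# Weighted simple linear regression in closed form.
wls_fit <- function(x, y, w) {
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0) return(NULL)
  beta <- sum(w * (x - xb) * (y - yb)) / sxx
  list(alpha = yb - beta * xb, beta = beta)
}

#' Threshold estimation by weighted semi-logarithmic regression
#'
#' Fits `log10(MEP) = alpha + beta * intensity` over the non-gated trials
#' whose amplitudes lie inside the linear window of the recruitment curve,
#' and returns the intensity at which the fit crosses the target amplitude.
#' The fit is iteratively reweighted (Tukey biweight, 3 iterations) so that
#' points lying closer to the regression line contribute more.
#'
#' @param trials Data frame with at least columns `ts_intensity`, `mep_mv`
#'   and `gated`.
#' @param target_mep Target amplitude (mV) whose crossing defines the
#'   threshold.
#' @param window Length-2 amplitude window (mV); trials outside it are
#'   excluded.
#' @return An object of class `threshold_estimate`: list with `value`
#'   (\%MSO; `NA` when invalid), `target_mep`, `n_trials_used`,
#'   `n_excluded`, `valid`, and the fitted `alpha`, `beta`.
#' @export
#' @examples
#' tr <- data.frame(ts_intensity = c(48, 52),
#'                  mep_mv = c(0.1, 0.4), gated = FALSE)
#' regression_threshold(tr, target_mep = 0.2)$value  # 50: log-midpoint
regression_threshold <- function(trials, target_mep = 0.2,
                                 window = c(0.02, 2.0)) {
  keep <- !trials$gated &
    trials$mep_mv >= window[1] & trials$mep_mv <= window[2]
  n_excluded <- nrow(trials) - sum(keep)
  invalid <- function() {
    structure(list(value = NA_real_, target_mep = target_mep,
                   n_trials_used = sum(keep), n_excluded = n_excluded,
                   valid = FALSE, alpha = NA_real_, beta = NA_real_),
              class = "threshold_estimate")
  }
  if (sum(keep) < 2) return(invalid())
  x <- trials$ts_intensity[keep]
  y <- log10(trials$mep_mv[keep])
  if (length(unique(x)) < 2) return(invalid())

  fit <- wls_fit(x, y, rep(1, length(x)))
  for (it in 1:3) {
    r <- y - (fit$alpha + fit$beta * x)
    s <- stats::median(abs(r)) / 0.6745
    if (s < 1e-10) break
    u <- r / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 2 || length(unique(x[w > 0])) < 2) break
    nf <- wls_fit(x, y, w)
    if (is.null(nf)) break
    fit <- nf
  }
  if (is.null(fit) || fit$beta <= 0) return(invalid())
  value <- (log10(target_mep) - fit$alpha) / fit$beta
  # a valid threshold must lie in the deliverable intensity range
  if (value < 0 || value > 100) return(invalid())
  structure(list(value = value, target_mep = target_mep,
                 n_trials_used = sum(keep), n_excluded = n_excluded,
                 valid = TRUE, alpha = fit$alpha, beta = fit$beta),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (x$valid)
    cat(sprintf("Threshold %.2f %%MSO (target %.2g mV, %d trials, %d excluded)\n",
                x$value, x$target_mep, x$n_trials_used, x$n_excluded))
  else
    cat(sprintf("Invalid threshold estimate (target %.2g mV, %d usable trials)\n",
                x$target_mep, x$n_trials_used))
  invisible(x)
}

#' Track a threshold on a virtual subject
#'
#' Runs the closed loop: deliver a stimulus, observe the MEP, adjust the
#' intensity with [proportional_step()], and count valid estimates with
#' [is_valid_estimate()].  Tracking is deemed stable once
#' `valid_estimates_required` valid estimates have accumulated (a safety cap
#' bounds the total trial count).  The threshold itself is then computed by
#' [regression_threshold()] over all non-gated trials.  Contaminated sweeps
#' (prestimulus EMG above the 0.015 mV gate) are recorded as gated and
#' redelivered at the same intensity.
#'
#' @param model An [excitability_model()].
#' @param cfg A [tracker_config()].
#' @param start_intensity Initial stimulus intensity (\%MSO).
#' @param drift Additive per-examination threshold drift (\%MSO).
#' @param prestim_gate_mv Prestimulus gating threshold (mV).
#' @return List with elements `estimate` (a `threshold_estimate`) and
#'   `trials` (data frame of delivered trials).
#' @export
track_threshold <- function(model, cfg = tracker_config(),
                            start_intensity, drift = 0,
                            prestim_gate_mv = 0.015) {
  if (start_intensity < 0 || start_intensity > 100)
    stop("'start_intensity' must be in [0, 100]", call. = FALSE)
  nmax <- cfg$max_trials
  intensity <- numeric(nmax); mep <- numeric(nmax); gated <- logical(nmax)
  cur <- start_intensity
  prev_mep <- NA_real_
  n_valid <- 0L
  i <- 0L
  while (n_valid < cfg$valid_estimates_required && i < nmax) {
    i <- i + 1L
    ev <- sample_prestim_event(model)
    if (ev$contaminated && !gate_prestimulus(ev$peak_mv, prestim_gate_mv)) {
      # discarded sweep: record it, keep the intensity, redeliver
      intensity[i] <- cur
      mep[i] <- generate_mep(model, cur, 0, drift)
      gated[i] <- TRUE
      next
    }
    m <- generate_mep(model, cur, 0, drift)
    intensity[i] <- cur; mep[i] <- m; gated[i] <- FALSE
    if (is_valid_estimate(prev_mep, m, cfg)) n_valid <- n_valid + 1L
    prev_mep <- m
    cur <- proportional_step(cur, m, cfg, mep_floor = model$mep_floor)
  }
  trials <- data.frame(trial_index = seq_len(i),
                       ts_intensity = intensity[seq_len(i)],
                       mep_mv = mep[seq_len(i)],
                       gated = gated[seq_len(i)])
  est <- regression_threshold(trials, cfg$target_mep, cfg$regression_window)
  if (n_valid < cfg$valid_estimates_required) est$valid <- FALSE
  if (!est$valid) est$value <- NA_real_
  list(estimate = est, trials = trials)
}
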