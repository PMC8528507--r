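#' Configuration of one SICI examination
#'
#' Defaults mirror the automated paired-pulse protocols: nine ISI
#' conditions (1--7 ms) each delivered 10 times plus 30 control stimuli, in
#' ten pseudorandomised cycles of the twelve conditions; conditioning
#' stimulus at 70\% of the tracked RMT; test stimulus starting at 120\% of
#' RMT (threshold-tracking variant) or fixed at TS_1mV (amplitude variant);
#' in-protocol tracking steps of 1 \%MSO; and a 0.015 mV prestimulus gate
#' applied 270 ms before the stimuli.
#'
#' @param isis ISIs in ms.
#' @param reps_per_isi Deliveries per ISI condition.
#' @param control_reps Total control (single-stimulus) deliveries; must be
#'   `reps_per_isi * n_control_channels`.
#' @param n_control_channels Number of interleaved control conditions (3).
#' @param cs_fraction Conditioning-stimulus intensity as a fraction of RMT.
#' @param ts_init_fraction Initial test-stimulus intensity as a fraction of
#'   RMT (threshold-tracking protocol).
#' @param channel_step In-protocol tracking step (\%MSO), doubled after two
#'   consecutive same-side misses.
#' @param target_mep Tracked target amplitude (mV).
#' @param tracking_error_tol Fractional log-scale tolerance defining a "hit".
#' @param regression_window Amplitude window (mV) for threshold regression.
#' @param prestim_gate_mv Prestimulus EMG gate (mV); sweeps with peaks
#'   exceeding it are discarded.
#' @param prestim_window_ms Prestimulus window (ms), recorded as metadata.
#' @param band_1_3.5,band_1_7 ISI membership of the two averaged SICI bands.
#' @param max_redeliveries_per_cycle Cap on gated-sweep redeliveries queued
#'   within one cycle.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(isis = c(1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 7),
                            reps_per_isi = 10,
                            control_reps = 30,
                            n_control_channels = 3,
                            cs_fraction = 0.70,
                            ts_init_fraction = 1.20,
                            channel_step = 1,
                            target_mep = 0.2,
                            tracking_error_tol = 0.2,
                            regression_window = c(0.02, 2.0),
                            prestim_gate_mv = 0.015,
                            prestim_window_ms = 270,
                            band_1_3.5 = c(1, 1.5, 2, 2.5, 3, 3.5),
                            band_1_7 = c(1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 7),
                            max_redeliveries_per_cycle = 24) {
  if (control_reps != reps_per_isi * n_control_channels)
    stop("'control_reps' must equal reps_per_isi * n_control_channels",
         call. = FALSE)
  structure(
    list(isis = isis, reps_per_isi = as.integer(reps_per_isi),
         control_reps = as.integer(control_reps),
         n_control_channels = as.integer(n_control_channels),
         cs_fraction = cs_fraction, ts_init_fraction = ts_init_fraction,
         channel_step = channel_step, target_mep = target_mep,
         tracking_error_tol = tracking_error_tol,
         regression_window = regression_window,
         prestim_gate_mv = prestim_gate_mv,
         prestim_window_ms = prestim_window_ms,
         band_1_3.5 = band_1_3.5, band_1_7 = band_1_7,
         max_redeliveries_per_cycle = as.integer(max_redeliveries_per_cycle)),
    class = "protocol_config")
}

#' Pseudorandomised delivery schedule
#'
#' Builds `reps_per_isi` cycles, each an independent random permutation of
#' the twelve conditions (nine ISIs plus three control slots), so that every
#' ISI appears exactly `reps_per_isi` times and controls `control_reps`
#' times in total.
#'
#' @param cfg A [protocol_config()].
#' @return Data frame with columns `cycle`, `position`, `condition`
#'   (character: the ISI in ms, or `"control1"`..`"control3"`).
#' @export
build_schedule <- function(cfg = protocol_config()) {
  conds <- c(as.character(cfg$isis),
             paste0("control", seq_len(cfg$n_control_channels)))
  cycles <- lapply(seq_len(cfg$reps_per_isi), function(cy) {
    data.frame(cycle = cy, position = seq_along(conds),
               condition = sample(conds))
  })
  do.call(rbind, cycles)
}

#' Prestimulus EMG gate
#'
#' Keeps a sweep unless its negative prestimulus EMG peak exceeds the gate;
#' a peak exactly at the gate is kept (strict "exceeding" discards).
#'
#' @param peak_mv Prestimulus peak amplitude (mV, >= 0).
#' @param gate_mv Gate level (mV), or a [protocol_config()].
#' @return Logical: `TRUE` to keep the sweep.
#' @export
gate_prestimulus <- function(peak_mv, gate_mv = 0.015) {
  if (inherits(gate_mv, "protocol_config")) gate_mv <- gate_mv$prestim_gate_mv
  peak_mv <= gate_mv
}

#' Threshold-tracking SICI from a conditioned threshold
#'
#' `T-SICI = (conditioned threshold - RMT) / RMT x 100\%`: positive values
#' are inhibition (the conditioned threshold is elevated), negative values
#' facilitation.
#'
#' @param conditioned_threshold Conditioned threshold (\%MSO).
#' @param rmt Resting motor threshold (\%MSO), > 0.
#' @return T-SICI in \% of RMT.
#' @export
compute_t_sici <- function(conditioned_threshold, rmt) {
  if (any(rmt <= 0)) stop("'rmt' must be > 0", call. = FALSE)
  (conditioned_threshold - rmt) / rmt * 100
}

geomean <- function(x) exp(mean(log(x)))

#' Amplitude SICI from conditioned and control MEPs
#'
#' `A-SICI = geomean(conditioned MEP) / geomean(control MEP) x 100\%`:
#' values below 100 are inhibition, above 100 facilitation.  Returns `NA`
#' when either list is empty after gating.
#'
#' @param conditioned_meps,control_meps Positive MEP amplitudes (mV).
#' @return A-SICI in \% of the control MEP.
#' @export
compute_a_sici <- function(conditioned_meps, control_meps) {
  if (length(conditioned_meps) == 0 || length(control_meps) == 0)
    return(NA_real_)
  100 * geomean(conditioned_meps) / geomean(control_meps)
}

isi_delta_abs <- function(model, isi) {
  d <- model$inhibition_profile[as.character(isi)]
  if (is.na(d)) stop(sprintf("no inhibition profile entry for ISI %s ms", isi),
                     call. = FALSE)
  unname(d) / 100 * model$theta_true
}

band_mean_t <- function(sici, isis, band) {
  # averaged over the member ISIs with usable estimates; an exam with any
  # missing ISI is still flagged invalid overall
  v <- sici[as.character(intersect(isis, band))]
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

new_examination_result <- function(protocol, rmt, ts_1mv, sici,
                                   band135, band17, trials, gated_count,
                                   valid = TRUE) {
  structure(list(protocol = protocol, rmt_0_2 = rmt, ts_1mv = ts_1mv,
                 sici = sici, band_1_3.5 = band135, band_1_7 = band17,
                 trials = trials, gated_count = gated_count, valid = valid),
            class = "examination_result")
}

#' @export
print.examination_result <- function(x, ...) {
  cat(sprintf("%s-SICI examination (%svalid)\n", x$protocol,
              if (x$valid) "" else "in"))
  cat(sprintf("  RMT_0.2mV = %.1f %%MSO", x$rmt_0_2))
  if (!is.na(x$ts_1mv)) cat(sprintf(", TS_1mV = %.1f %%MSO", x$ts_1mv))
  cat("\n  per-ISI SICI:\n")
  print(round(x$sici, 1))
  cat(sprintf("  bands: 1-3.5 ms = %.1f, 1-7 ms = %.1f; %d gated sweeps\n",
              x$band_1_3.5, x$band_1_7, x$gated_count))
  invisible(x)
}

# Shared trial-log accumulator used by both protocol runners.
trial_log <- function(nmax) {
  list(n = 0L,
       trial_index = integer(nmax), cycle = integer(nmax),
       condition = character(nmax), cs_intensity = numeric(nmax),
       ts_intensity = numeric(nmax), mep_mv = numeric(nmax),
       gated = logical(nmax))
}

log_add <- function(lg, cycle, condition, cs, ts, mep, gated) {
  i <- lg$n + 1L
  lg$n <- i
  lg$trial_index[i] <- i; lg$cycle[i] <- cycle; lg$condition[i] <- condition
  lg$cs_intensity[i] <- cs; lg$ts_intensity[i] <- ts
  lg$mep_mv[i] <- mep; lg$gated[i] <- gated
  lg
}

log_df <- function(lg) {
  i <- seq_len(lg$n)
  data.frame(trial_index = lg$trial_index[i], cycle = lg$cycle[i],
             condition = lg$condition[i], cs_intensity = lg$cs_intensity[i],
             ts_intensity = lg$ts_intensity[i], mep_mv = lg$mep_mv[i],
             gated = lg$gated[i], time_s = 5 * (i - 1))
}

# Channel threshold with a tracking-equilibrium fallback.  A continuously
# tracked channel spends its trials in a narrow band around the threshold,
# so the regression design can be (near-)singular: the fitted slope is then
# non-positive or the intersection leaves the deliverable range.  In that
# case the proportional controller itself is the estimator -- its feedback
# centres the delivered intensity on the intensity whose expected log MEP
# equals the target -- so the mean of the later delivered intensities
# (second half, to shed the approach path) is used.
channel_threshold <- function(tr, cfg, log_tol) {
  est <- regression_threshold(tr, cfg$target_mep, cfg$regression_window)
  if (est$valid) return(est$value)
  x <- tr$ts_intensity[!tr$gated]
  if (length(x) < 2) return(NA_real_)
  mean(x[ceiling(length(x) / 2):length(x)])
}

#' Run one threshold-tracking (T-SICI) examination
#'
#' The nine conditioned thresholds are tracked on independent channels,
#' starting at `ts_init_fraction` of the tracked RMT, with a fixed step of
#' `channel_step` \%MSO that is doubled after two consecutive same-side
#' misses of the 0.2 mV target and reset once the MEP lands within the
#' tracking tolerance.  RMT is continuously tracked on three interleaved
#' control channels using proportional 1 \%MSO steps.  After each
#' pseudorandomisation cycle the conditioning stimulus is recomputed as
#' `cs_fraction` times the mean of the three control-channel estimates.
#' Gated sweeps are redelivered at the end of the current cycle so per-ISI
#' counts stay fixed.  Thresholds (per-ISI conditioned, and the control RMT
#' from the pooled control trials) are estimated by
#' [regression_threshold()], and per-ISI SICI by [compute_t_sici()].
#'
#' @param model An [excitability_model()].
#' @param rmt_estimate Tracked RMT (\%MSO) obtained before the protocol.
#' @param cfg A [protocol_config()].
#' @param drift Per-examination threshold drift (\%MSO).
#' @return An `examination_result`.
#' @export
run_t_sici <- function(model, rmt_estimate, cfg = protocol_config(),
                       drift = 0) {
  if (is.na(rmt_estimate) || rmt_estimate <= 0)
    stop("'rmt_estimate' must be a valid positive threshold", call. = FALSE)
  isis <- as.character(cfg$isis)
  ts <- stats::setNames(
    rep(min(cfg$ts_init_fraction * rmt_estimate, 100), length(isis)), isis)
  miss_sign <- stats::setNames(integer(length(isis)), isis)
  miss_run <- stats::setNames(integer(length(isis)), isis)
  ctrl_int <- rep(rmt_estimate, cfg$n_control_channels)
  ctrl_cfg <- tracker_config(target_mep = cfg$target_mep, max_step = 1,
                             tracking_error_tol = cfg$tracking_error_tol,
                             regression_window = cfg$regression_window)
  cs <- cfg$cs_fraction * rmt_estimate
  schedule <- build_schedule(cfg)
  log_tol <- log10(1 + cfg$tracking_error_tol)

  lg <- trial_log(nrow(schedule) + cfg$reps_per_isi *
                    cfg$max_redeliveries_per_cycle)
  gated_count <- 0L

  for (cy in seq_len(cfg$reps_per_isi)) {
    queue <- schedule$condition[schedule$cycle == cy]
    redeliveries <- 0L
    while (length(queue) > 0) {
      cond <- queue[1]; queue <- queue[-1]
      is_ctrl <- startsWith(cond, "control")
      intensity <- if (is_ctrl) {
        ctrl_int[as.integer(substring(cond, 8))]
      } else ts[cond]
      delta <- if (is_ctrl) 0 else isi_delta_abs(model, cond)
      ev <- sample_prestim_event(model)
      gated <- ev$contaminated && !gate_prestimulus(ev$peak_mv, cfg)
      mep <- generate_mep(model, intensity, delta, drift)
      lg <- log_add(lg, cy, cond, if (is_ctrl) NA_real_ else cs,
                    intensity, mep, gated)
      if (gated) {
        gated_count <- gated_count + 1L
        if (redeliveries < cfg$max_redeliveries_per_cycle) {
          queue <- c(queue, cond)
          redeliveries <- redeliveries + 1L
        }
        next
      }
      if (is_ctrl) {
        k <- as.integer(substring(cond, 8))
        ctrl_int[k] <- proportional_step(ctrl_int[k], mep, ctrl_cfg,
                                         mep_floor = model$mep_floor)
      } else {
        lerr <- log10(mep / cfg$target_mep)
        if (abs(lerr) <= log_tol) {
          miss_run[cond] <- 0L; miss_sign[cond] <- 0L
        } else {
          dir <- if (lerr > 0) -1L else 1L  # above target -> decrease
          if (miss_sign[cond] == dir) miss_run[cond] <- miss_run[cond] + 1L
          else miss_run[cond] <- 1L
          miss_sign[cond] <- dir
          step <- cfg$channel_step * if (miss_run[cond] >= 2) 2 else 1
          ts[cond] <- min(max(ts[cond] + dir * step, 0), 100)
        }
      }
    }
    # CS follows the average control-channel RMT estimate after each cycle
    trials_so_far <- log_df(lg)
    ctrl_est <- vapply(seq_len(cfg$n_control_channels), function(k) {
      tr <- trials_so_far[trials_so_far$condition == paste0("control", k), ]
      est <- regression_threshold(tr, cfg$target_mep, cfg$regression_window)
      if (est$valid) est$value else ctrl_int[k]
    }, numeric(1))
    cs <- cfg$cs_fraction * mean(ctrl_est)
  }

  trials <- log_df(lg)
  ctrl_trials <- trials[startsWith(trials$condition, "control"), ]
  rmt_val <- channel_threshold(ctrl_trials, cfg, log_tol)
  sici <- stats::setNames(rep(NA_real_, length(isis)), isis)
  if (!is.na(rmt_val)) {
    for (cond in isis) {
      tr <- trials[trials$condition == cond, ]
      sici[cond] <- compute_t_sici(channel_threshold(tr, cfg, log_tol),
                                   rmt_val)
    }
  }
  new_examination_result(
    protocol = "T", rmt = rmt_val, ts_1mv = NA_real_, sici = sici,
    band135 = band_mean_t(sici, cfg$isis, cfg$band_1_3.5),
    band17 = band_mean_t(sici, cfg$isis, cfg$band_1_7),
    trials = trials, gated_count = gated_count,
    valid = !is.na(rmt_val) && !anyNA(sici))
}

#' Run one automated conventional (A-SICI) examination
#'
#' All stimulus intensities are fixed for the whole examination: the
#' conditioning stimulus at `cs_fraction` of the tracked RMT and the test
#' stimulus (for both conditioned and control sweeps) at TS_1mV.  Per-ISI
#' SICI is the geometric-mean conditioned/control MEP ratio in percent
#' ([compute_a_sici()]); band values are geometric-mean ratios over all
#' member-ISI sweeps.  Gated sweeps are redelivered at the end of the
#' current cycle.
#'
#' @param model An [excitability_model()].
#' @param rmt_estimate Tracked RMT (\%MSO), sets the conditioning intensity.
#' @param ts1mv_estimate Tracked TS_1mV (\%MSO), the fixed test intensity.
#' @param cfg A [protocol_config()].
#' @param drift Per-examination threshold drift (\%MSO).
#' @return An `examination_result`.
#' @export
run_a_sici <- function(model, rmt_estimate, ts1mv_estimate,
                       cfg = protocol_config(), drift = 0) {
  if (is.na(rmt_estimate) || rmt_estimate <= 0 ||
      is.na(ts1mv_estimate) || ts1mv_estimate <= 0)
    stop("valid 'rmt_estimate' and 'ts1mv_estimate' are required",
         call. = FALSE)
  cs <- cfg$cs_fraction * rmt_estimate
  ts <- min(ts1mv_estimate, 100)
  schedule <- build_schedule(cfg)
  lg <- trial_log(nrow(schedule) + cfg$reps_per_isi *
                    cfg$max_redeliveries_per_cycle)
  gated_count <- 0L
  for (cy in seq_len(cfg$reps_per_isi)) {
    queue <- schedule$condition[schedule$cycle == cy]
    redeliveries <- 0L
    while (length(queue) > 0) {
      cond <- queue[1]; queue <- queue[-1]
      is_ctrl <- startsWith(cond, "control")
      delta <- if (is_ctrl) 0 else isi_delta_abs(model, cond)
      ev <- sample_prestim_event(model)
      gated <- ev$contaminated && !gate_prestimulus(ev$peak_mv, cfg)
      mep <- generate_mep(model, ts, delta, drift)
      lg <- log_add(lg, cy, cond, if (is_ctrl) NA_real_ else cs,
                    ts, mep, gated)
      if (gated) {
        gated_count <- gated_count + 1L
        if (redeliveries < cfg$max_redeliveries_per_cycle) {
          queue <- c(queue, cond)
          redeliveries <- redeliveries + 1L
        }
      }
    }
  }
  trials <- log_df(lg)
  ok <- !trials$gated
  ctrl_meps <- trials$mep_mv[ok & startsWith(trials$condition, "control")]
  isis <- as.character(cfg$isis)
  sici <- stats::setNames(vapply(isis, function(cond) {
    compute_a_sici(trials$mep_mv[ok & trials$condition == cond], ctrl_meps)
  }, numeric(1)), isis)
  band_a <- function(band) {
    members <- as.character(intersect(cfg$isis, band))
    compute_a_sici(trials$mep_mv[ok & trials$condition %in% members],
                   ctrl_meps)
  }
  new_examination_result(
    protocol = "A", rmt = rmt_estimate, ts_1mv = ts1mv_estimate,
    sici = sici, band135 = band_a(cfg$band_1_3.5), band17 = band_a(cfg$band_1_7),
    trials = trials, gated_count = gated_count, valid = !anyNA(sici))
}
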