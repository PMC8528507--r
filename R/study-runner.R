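#' Multi-session test-retest study design
#'
#' The default design: two examination days (5--7 days apart, metadata
#' only), a morning and an afternoon session on each day, each protocol run
#' twice per session by observer 1 (8 intraobserver examinations per
#' protocol per subject), plus one additional examination per protocol by a
#' second observer appended to one session (9 examinations per protocol in
#' total).
#'
#' @param days Number of examination days.
#' @param sessions_per_day Sessions per day (1 = morning only, 2 = morning
#'   and afternoon).
#' @param exams_per_session Repeats of each protocol within a session.
#' @param protocols Protocols to run, subset of `c("T", "A")`.
#' @param interobserver Run the second-observer examinations?
#' @param interobserver_day,interobserver_session Session to which the
#'   second-observer examinations are appended; by default day 1, last
#'   session of that day.
#' @param interday_gap_days Gap between days (metadata).
#' @return An object of class `study_design`.
#' @export
study_design <- function(days = 2, sessions_per_day = 2,
                         exams_per_session = 2, protocols = c("T", "A"),
                         interobserver = TRUE,
                         interobserver_day = 1,
                         interobserver_session = sessions_per_day,
                         interday_gap_days = 6) {
  if (interobserver &&
      (interobserver_day > days || interobserver_session > sessions_per_day))
    stop("interobserver session outside the design", call. = FALSE)
  structure(
    list(days = as.integer(days),
         sessions_per_day = as.integer(sessions_per_day),
         exams_per_session = as.integer(exams_per_session),
         protocols = protocols, interobserver = interobserver,
         interobserver_day = as.integer(interobserver_day),
         interobserver_session = as.integer(interobserver_session),
         interday_gap_days = interday_gap_days),
    class = "study_design")
}

#' Number of intraobserver examinations per subject per protocol
#' @param design A [study_design()].
#' @return Integer count (days x sessions x repeats).
#' @export
intraobserver_exams <- function(design) {
  design$days * design$sessions_per_day * design$exams_per_session
}

# One complete examination: per-exam drift, RMT tracking, optional TS_1mV
# tracking, then the protocol.  Returns NULL components on threshold
# failure.  `observer_offset` models a systematic observer effect as an
# additive shift of all delivered intensities' reference point.
run_one_examination <- function(model, protocol, cfg, observer_offset = 0) {
  drift <- stats::rnorm(1, 0, model$session_drift_sd) + observer_offset
  start <- min(95, model$theta_true + drift + 7)
  rmt_trk <- track_threshold(model, tracker_config(target_mep = 0.2),
                             start_intensity = max(start, 0), drift = drift)
  if (!rmt_trk$estimate$valid) return(NULL)
  rmt <- rmt_trk$estimate$value
  if (protocol == "T") {
    res <- run_t_sici(model, rmt, cfg, drift = drift)
  } else {
    ts_trk <- track_threshold(model, tracker_config(target_mep = 1.0),
                              start_intensity = min(1.2 * rmt, 100),
                              drift = drift)
    if (!ts_trk$estimate$valid) return(NULL)
    res <- run_a_sici(model, rmt, ts_trk$estimate$value, cfg, drift = drift)
  }
  res
}

#' Run a complete simulated test-retest study
#'
#' Draws a virtual cohort and executes the full design: for every subject,
#' day, session and repeat, a fresh examination (threshold estimation
#' followed by the protocol), plus the second-observer examinations.  The
#' whole study is reproducible from `seed`.
#'
#' @param params A [cohort_params()].
#' @param design A [study_design()].
#' @param cfg A [protocol_config()].
#' @param seed Integer seed for the whole study.
#' @param observer2_offset SD-free additive intensity offset of observer 2
#'   (\%MSO); 0 by default, as no systematic observer bias is modelled.
#' @return An object of class `study_dataset`: list with `results` (long
#'   data frame: subject, protocol, observer, day, session, rep,
#'   exam_index, parameter, value), `examinations` (list of
#'   `examination_result` objects with metadata), `cohort`, and the
#'   generating configuration.
#' @export
run_study <- function(params = cohort_params(), design = study_design(),
                      cfg = protocol_config(), seed = 1,
                      observer2_offset = 0) {
  set.seed(seed)
  p2 <- params
  p2$seed <- NULL
  cohort <- sample_cohort(p2)

  exams <- list()
  rows <- list()
  ei <- 0L
  for (s in seq_along(cohort)) {
    model <- cohort[[s]]
    for (day in seq_len(design$days)) {
      for (session in seq_len(design$sessions_per_day)) {
        for (rep in seq_len(design$exams_per_session)) {
          for (protocol in design$protocols) {
            ei <- ei + 1L
            res <- run_one_examination(model, protocol, cfg)
            exam_index <- (day - 1) * design$sessions_per_day *
              design$exams_per_session +
              (session - 1) * design$exams_per_session + rep
            exams[[ei]] <- list(subject = s, observer = 1L, day = day,
                                session = session, rep = rep,
                                exam_index = exam_index,
                                protocol = protocol, result = res)
            rows[[ei]] <- result_rows(s, 1L, day, session, rep, exam_index,
                                      protocol, res, cfg)
          }
        }
        if (design$interobserver && day == design$interobserver_day &&
            session == design$interobserver_session) {
          for (protocol in design$protocols) {
            ei <- ei + 1L
            res <- run_one_examination(model, protocol, cfg,
                                       observer_offset = observer2_offset)
            exams[[ei]] <- list(subject = s, observer = 2L, day = day,
                                session = session, rep = 1L,
                                exam_index = NA_integer_,
                                protocol = protocol, result = res)
            rows[[ei]] <- result_rows(s, 2L, day, session, 1L, NA_integer_,
                                      protocol, res, cfg)
          }
        }
      }
    }
  }
  structure(list(results = do.call(rbind, rows), examinations = exams,
                 cohort = cohort, params = params, design = design,
                 cfg = cfg, seed = seed),
            class = "study_dataset")
}

# Long-format parameter rows for one examination.
result_rows <- function(subject, observer, day, session, rep, exam_index,
                        protocol, res, cfg) {
  isis <- as.character(cfg$isis)
  pars <- c("RMT_0.2mV", "TS_1mV", paste0("SICI_", isis, "ms"),
            "SICI_1-3.5ms", "SICI_1-7ms")
  if (is.null(res)) {
    vals <- rep(NA_real_, length(pars))
  } else {
    vals <- c(res$rmt_0_2, res$ts_1mv, unname(res$sici[isis]),
              res$band_1_3.5, res$band_1_7)
  }
  data.frame(subject = subject, observer = observer, day = day,
             session = session, rep = rep, exam_index = exam_index,
             protocol = protocol, parameter = pars, value = vals)
}

#' @export
print.study_dataset <- function(x, ...) {
  n_ex <- length(x$examinations)
  n_fail <- sum(vapply(x$examinations, function(e) is.null(e$result),
                       logical(1)))
  cat(sprintf("Simulated SICI study: %d subjects, %d examinations (%d failed), seed %d\n",
              length(x$cohort), n_ex, n_fail, x$seed))
  invisible(x)
}

# Extract a subjects x exams measurement matrix for one parameter.
# `exam_indices` selects observer-1 exam indices (columns in that order).
study_matrix <- function(ds, protocol, parameter, exam_indices,
                         observer = 1L) {
  r <- ds$results
  r <- r[r$protocol == protocol & r$parameter == parameter &
           r$observer == observer & r$exam_index %in% exam_indices, ]
  subjects <- sort(unique(ds$results$subject))
  m <- matrix(NA_real_, length(subjects), length(exam_indices),
              dimnames = list(subjects, exam_indices))
  for (i in seq_len(nrow(r)))
    m[as.character(r$subject[i]), as.character(r$exam_index[i])] <- r$value[i]
  m
}

# log10-transform A-SICI style parameters (positive amplitude ratios).
is_log_parameter <- function(protocol, parameter) {
  protocol == "A" && startsWith(parameter, "SICI")
}

#' Extract a subjects-by-repeats measurement matrix from a study
#'
#' Pulls one parameter's values for the selected observer-1 examination
#' indices into a [measurement_matrix()], applying the log10 transform for
#' amplitude-ratio (A-SICI) parameters and listwise deletion of subjects
#' with missing cells.
#'
#' @param ds A `study_dataset` from [run_study()].
#' @param protocol `"T"` or `"A"`.
#' @param parameter Parameter name as in `ds$results` (e.g. `"SICI_1ms"`,
#'   `"RMT_0.2mV"`, `"SICI_1-3.5ms"`).
#' @param exam_indices Intraobserver examination indices (columns).
#' @param observer Observer whose examinations are extracted.
#' @return A [measurement_matrix()].
#' @export
study_measurement_matrix <- function(ds, protocol, parameter, exam_indices,
                                     observer = 1L) {
  m <- study_matrix(ds, protocol, parameter, exam_indices, observer)
  scale <- if (is_log_parameter(protocol, parameter)) "log10" else "linear"
  if (scale == "log10") m <- log10(m)
  suppressMessages(
    measurement_matrix(m, parameter = parameter, scale = scale))
}

study_mm <- study_measurement_matrix

default_report_parameters <- function(protocol) {
  pars <- c("SICI_1ms", "SICI_2.5ms", "SICI_3ms", "SICI_1-3.5ms",
            "SICI_1-7ms", "RMT_0.2mV")
  if (protocol == "A") pars <- c(pars, "TS_1mV")
  pars
}

#' Reliability summary of a simulated study
#'
#' For each protocol and parameter of interest (SICI at 1, 2.5 and 3 ms,
#' the 1--3.5 and 1--7 ms bands, RMT and, for the amplitude protocol,
#' TS_1mV) computes: intraday coefficients of repeatability per session
#' (the two within-session repeats), intraday ICC(2,1) per day (morning
#' pair, afternoon pair, and first-morning vs first-afternoon), interday
#' ICC (first examinations of matching sessions across days), and, when
#' second-observer examinations exist, the interobserver ICC and paired t
#' test against observer 1's first examination of the matching session.
#' Amplitude-ratio parameters are analysed on the log10 scale, so their CRs
#' also carry back-transformed fold-change values.
#'
#' @param ds A `study_dataset` from [run_study()].
#' @return Tidy data frame: `protocol`, `parameter`, `analysis`,
#'   `statistic`, `value`, `ci_low`, `ci_high`, `band`, `n`.
#' @export
summarize_reliability <- function(ds) {
  design <- ds$design
  reps <- design$exams_per_session
  out <- list()
  add <- function(protocol, parameter, analysis, statistic, value,
                  ci = c(NA, NA), band = NA_character_, n = NA) {
    out[[length(out) + 1L]] <<- data.frame(
      protocol = protocol, parameter = parameter, analysis = analysis,
      statistic = statistic, value = value, ci_low = ci[1], ci_high = ci[2],
      band = band, n = n)
  }
  session_exams <- function(day, session) {
    base <- (day - 1) * design$sessions_per_day * reps + (session - 1) * reps
    base + seq_len(reps)
  }
  for (protocol in design$protocols) {
    for (parameter in default_report_parameters(protocol)) {
      lg <- is_log_parameter(protocol, parameter)
      # intraday CR: the two repeats within each session
      if (reps >= 2) {
        for (day in seq_len(design$days)) {
          for (session in seq_len(design$sessions_per_day)) {
            mm <- study_mm(ds, protocol, parameter,
                           session_exams(day, session))
            if (nrow(mm) >= 2) {
              cr <- coefficient_of_repeatability(mm)
              lab <- sprintf("intraday_cr_day%d_%s", day,
                             c("morning", "afternoon")[session])
              if (lg) add(protocol, parameter, lab, "cr_ratio",
                          cr$cr_ratio, cr$ci_ratio, n = nrow(mm))
              else add(protocol, parameter, lab, "cr", cr$cr, cr$ci,
                       n = nrow(mm))
            }
          }
        }
      }
      # intraday ICC per day: morning pair, afternoon pair, first
      # morning vs first afternoon
      if (design$sessions_per_day >= 2) {
        for (day in seq_len(design$days)) {
          sets <- list(morning = session_exams(day, 1),
                       afternoon = session_exams(day, 2),
                       morning_afternoon = c(session_exams(day, 1)[1],
                                             session_exams(day, 2)[1]))
          for (nm in names(sets)) {
            mm <- study_mm(ds, protocol, parameter, sets[[nm]])
            if (nrow(mm) >= 2) {
              ic <- icc_2_1(mm)
              add(protocol, parameter,
                  sprintf("intraday_icc_day%d_%s", day, nm), "icc",
                  ic$icc, ic$ci, ic$band, n = nrow(mm))
            }
          }
        }
      }
      # interday ICC: first exams of matching sessions across days
      if (design$days >= 2) {
        sets <- list(morning = c(session_exams(1, 1)[1],
                                 session_exams(2, 1)[1]))
        if (design$sessions_per_day >= 2) {
          sets$afternoon <- c(session_exams(1, 2)[1],
                              session_exams(2, 2)[1])
          sets$morning_afternoon <- c(session_exams(1, 1)[1],
                                      session_exams(2, 2)[1])
        }
        for (nm in names(sets)) {
          mm <- study_mm(ds, protocol, parameter, sets[[nm]])
          if (nrow(mm) >= 2) {
            ic <- icc_2_1(mm)
            add(protocol, parameter, sprintf("interday_icc_%s", nm),
                "icc", ic$icc, ic$ci, ic$band, n = nrow(mm))
          }
        }
      }
      # interobserver: observer 2 vs observer 1's first exam of the
      # matching session
      if (design$interobserver) {
        ref_idx <- session_exams(design$interobserver_day,
                                 design$interobserver_session)[1]
        m1 <- study_matrix(ds, protocol, parameter, ref_idx, observer = 1L)
        r2 <- ds$results
        r2 <- r2[r2$protocol == protocol & r2$parameter == parameter &
                   r2$observer == 2L, ]
        subjects <- sort(unique(ds$results$subject))
        v2 <- stats::setNames(rep(NA_real_, length(subjects)), subjects)
        v2[as.character(r2$subject)] <- r2$value
        m <- cbind(obs1 = m1[, 1], obs2 = v2)
        if (lg) m <- log10(m)
        mm <- suppressMessages(measurement_matrix(
          m, parameter, scale = if (lg) "log10" else "linear"))
        if (nrow(mm) >= 3) {
          ic <- icc_2_1(mm)
          add(protocol, parameter, "interobserver_icc", "icc", ic$icc,
              ic$ci, ic$band, n = nrow(mm))
          tt <- stats::t.test(mm[, 1], mm[, 2], paired = TRUE)
          add(protocol, parameter, "interobserver_paired_t", "p",
              tt$p.value, n = nrow(mm))
        }
      }
      # omnibus reproducibility across all intraobserver exams
      all_idx <- seq_len(intraobserver_exams(design))
      if (length(all_idx) >= 2) {
        mm <- study_mm(ds, protocol, parameter, all_idx)
        if (nrow(mm) > 2) {
          an <- suppressWarnings(rm_anova(mm))
          add(protocol, parameter, "rmanova", "F", an$F, n = nrow(mm))
          add(protocol, parameter, "rmanova", "p", an$p, n = nrow(mm))
          add(protocol, parameter, "rmanova", "epsilon", an$epsilon,
              n = nrow(mm))
          add(protocol, parameter, "rmanova", "mauchly_p", an$mauchly_p,
              n = nrow(mm))
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Group-level SICI curves and inter-method relationship
#'
#' Per-subject point estimates are obtained by averaging each subject's
#' intraobserver examinations -- arithmetically for threshold-tracking SICI,
#' geometrically for amplitude SICI -- then summarised per ISI as the group
#' mean with a one-sample t test against the control condition (0 \%RMT for
#' T-SICI; 100\% test MEP, tested on the log10 scale, for A-SICI).  When
#' both protocols are present, the inter-method regression of T-SICI on
#' log10 A-SICI is computed per ISI (across subjects) and pooled across
#' ISIs (on the group means).
#'
#' @param ds A `study_dataset` from [run_study()].
#' @return List with `curves` (data frame per protocol x ISI: group mean,
#'   SEM, t, p, significance), `subject_means` (subject x ISI x protocol),
#'   `per_isi_regression`, and `pooled_regression`.
#' @export
summarize_group_curves <- function(ds) {
  isis <- ds$cfg$isis
  subjects <- sort(unique(ds$results$subject))
  r <- ds$results[ds$results$observer == 1L, ]

  subj_mean <- function(protocol, isi) {
    parameter <- paste0("SICI_", isi, "ms")
    vapply(subjects, function(s) {
      v <- r$value[r$subject == s & r$protocol == protocol &
                     r$parameter == parameter]
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NA_real_)
      if (protocol == "A") geomean(v) else mean(v)
    }, numeric(1))
  }

  curves <- list(); smeans <- list()
  for (protocol in ds$design$protocols) {
    for (isi in isis) {
      sm <- subj_mean(protocol, isi)
      smeans[[paste(protocol, isi)]] <-
        data.frame(protocol = protocol, isi = isi, subject = subjects,
                   mean = sm)
      ok <- sm[!is.na(sm)]
      if (protocol == "A") {
        lt <- one_sample_condition_test(log10(ok), log10(100))
        gm <- 10^mean(log10(ok))
        sem <- 10^(stats::sd(log10(ok)) / sqrt(length(ok)))
        direction <- if (gm < 100) "inhibition" else "facilitation"
      } else {
        lt <- one_sample_condition_test(ok, 0)
        gm <- mean(ok)
        sem <- stats::sd(ok) / sqrt(length(ok))
        direction <- if (gm > 0) "inhibition" else "facilitation"
      }
      curves[[paste(protocol, isi)]] <- data.frame(
        protocol = protocol, isi = isi, group_mean = gm, sem = sem,
        t = lt$t, p = lt$p, significant = lt$p < 0.05,
        direction = direction, n = length(ok))
    }
  }
  curves <- do.call(rbind, curves)
  smeans <- do.call(rbind, smeans)
  rownames(curves) <- rownames(smeans) <- NULL

  per_isi <- NULL; pooled <- NULL
  if (all(c("T", "A") %in% ds$design$protocols)) {
    per_isi <- do.call(rbind, lapply(isis, function(isi) {
      tv <- smeans$mean[smeans$protocol == "T" & smeans$isi == isi]
      av <- smeans$mean[smeans$protocol == "A" & smeans$isi == isi]
      ok <- !is.na(tv) & !is.na(av)
      if (sum(ok) < 3) return(NULL)
      mr <- method_regression(tv[ok], av[ok])
      data.frame(isi = isi, slope = mr$slope, intercept = mr$intercept,
                 r = mr$r, r2 = mr$r2, n = mr$n)
    }))
    gt <- curves$group_mean[curves$protocol == "T"]
    ga <- curves$group_mean[curves$protocol == "A"]
    pooled <- method_regression(gt, ga)
  }
  list(curves = curves, subject_means = smeans,
       per_isi_regression = per_isi, pooled_regression = pooled)
}
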