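#' Write study outputs as CSV files
#'
#' Writes one trial-log CSV per examination (columns `subject_id`,
#' `observer`, `day`, `session`, `exam_index`, `protocol`, `trial_index`,
#' `cycle`, `condition`, `cs_intensity`, `ts_intensity`, `mep_mv`, `gated`,
#' `time_s`; time advances 5 s per trial at the 0.2 Hz stimulation rate),
#' plus a study-level tidy `results.csv` of all parameter values.  All
#' files are headered, comma-separated, UTF-8, with `.` as decimal mark.
#'
#' @param ds A `study_dataset` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_trial_logs <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (ex in ds$examinations) {
    if (is.null(ex$result)) next
    tr <- ex$result$trials
    log <- data.frame(subject_id = ex$subject, observer = ex$observer,
                      day = ex$day, session = ex$session,
                      exam_index = ex$exam_index, protocol = ex$protocol,
                      tr)
    f <- file.path(dir, sprintf("trials_s%02d_obs%d_d%d_s%d_r%d_%s.csv",
                                ex$subject, ex$observer, ex$day, ex$session,
                                ex$rep, ex$protocol))
    utils::write.csv(log, f, row.names = FALSE, fileEncoding = "UTF-8")
    files <- c(files, f)
  }
  f <- file.path(dir, "results.csv")
  utils::write.csv(ds$results, f, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(files, f))
}

#' Read a study-level results table back for re-analysis
#'
#' Reads the tidy `results.csv` written by [write_trial_logs()] and wraps
#' it so that [summarize_reliability()] and [summarize_group_curves()] can
#' be re-run without re-simulating.  Design and protocol metadata are
#' reconstructed from the table (days, sessions, repeats, protocols, ISIs).
#'
#' @param dir Directory containing `results.csv`.
#' @return A `study_dataset` (without trial-level examinations or cohort).
#' @export
read_study_results <- function(dir) {
  f <- file.path(dir, "results.csv")
  if (!file.exists(f)) stop("no results.csv in ", dir, call. = FALSE)
  res <- utils::read.csv(f, fileEncoding = "UTF-8")
  obs1 <- res[res$observer == 1L, ]
  design <- study_design(
    days = max(obs1$day), sessions_per_day = max(obs1$session),
    exams_per_session = max(obs1$rep),
    protocols = sort(unique(res$protocol), decreasing = TRUE),
    interobserver = any(res$observer == 2L),
    interobserver_day = if (any(res$observer == 2L))
      res$day[res$observer == 2L][1] else 1L,
    interobserver_session = if (any(res$observer == 2L))
      res$session[res$observer == 2L][1] else 1L)
  isis <- sort(as.numeric(sub("ms$", "", sub("^SICI_", "",
    grep("^SICI_[0-9.]+ms$", unique(res$parameter), value = TRUE)))))
  structure(list(results = res, examinations = list(), cohort = list(),
                 params = NULL, design = design,
                 cfg = protocol_config(isis = isis), seed = NA_integer_),
            class = "study_dataset")
}

#' Write the tidy reliability report as CSV
#'
#' @param report Data frame from [summarize_reliability()].
#' @param file Output CSV path.
#' @return Invisibly, `file`.
#' @export
write_reliability_report <- function(report, file) {
  utils::write.csv(report, file, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}
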