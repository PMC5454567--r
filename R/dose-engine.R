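# Dose engine: personalized delta-t exercise doses, completion notifications
# with per-day debouncing, and weekly adherence reporting.

#' Dose prescription
#'
#' The personalized daily exercise dose: the delta-t (degrees C) a
#' participant reaches in 30 minutes of dosed MICT (100 +/- 10 BPM), plus the
#' calibration provenance.
#'
#' @param participant_id Participant identifier.
#' @param dose_threshold Daily dose, degrees C (> 0).
#' @param calibrated_at Timestamp of the calibration session.
#' @param calibration_session_id Identifier of the calibration session.
#' @param hr_center,hr_halfwidth Target HR band used in calibration.
#' @return An object of class `dose_prescription`.
#' @export
dose_prescription <- function(participant_id, dose_threshold,
                              calibrated_at = NA, calibration_session_id = NA,
                              hr_center = 100, hr_halfwidth = 10) {
  assert_num(dose_threshold, "dose_threshold", lower = 1e-12)
  structure(list(participant_id = as.character(participant_id),
                 dose_threshold = dose_threshold,
                 calibrated_at = calibrated_at,
                 calibration_session_id = calibration_session_id,
                 hr_center = hr_center, hr_halfwidth = hr_halfwidth),
            class = "dose_prescription")
}

#' @export
print.dose_prescription <- function(x, ...) {
  cat(sprintf("<dose_prescription> %s: %.2f C (calibrated %s)\n",
              x$participant_id, x$dose_threshold,
              if (inherits(x$calibrated_at, "POSIXct")) format_ts(x$calibrated_at)
              else as.character(x$calibrated_at)))
  invisible(x)
}

#' Calibrate a personalized exercise dose
#'
#' The dose is the delta-t reached at minute `duration` of a dosed-MICT
#' calibration bout: the numerical expression of the recommended 30 minutes
#' of moderate-intensity exercise. The calibration session must be classified
#' MICT, last at least `duration` minutes, and (when heart rate was recorded)
#' spend at least `min_band_fraction` of its post-burn-in minutes inside the
#' target band.
#'
#' @param metrics A [analyze_session()] result for the calibration session.
#' @param duration Dose definition horizon, minutes (default 30).
#' @param hr_center,hr_halfwidth Target band (default 100 +/- 10 BPM).
#' @param min_band_fraction Required in-band HR fraction after a 5-minute
#'   burn-in (default 0.8).
#' @param participant_id Overrides the id recorded in the prescription.
#' @return A [dose_prescription()].
#' @export
calibrate_dose <- function(metrics, duration = 30,
                           hr_center = 100, hr_halfwidth = 10,
                           min_band_fraction = 0.8,
                           participant_id = NULL) {
  if (!inherits(metrics, "session_metrics")) {
    ld_stop("`metrics` must be a session_metrics object",
            "legdose_calibration_error")
  }
  if (!identical(metrics$regimen, "MICT")) {
    ld_stop(sprintf("calibration session must be MICT (got %s)",
                    metrics$regimen), "legdose_calibration_error")
  }
  tr <- metrics$delta_t
  if (max(tr$minute) < duration) {
    ld_stop(sprintf("calibration session is shorter than %d minutes", duration),
            "legdose_calibration_error")
  }
  hr <- tr$heart_rate_bpm
  chk <- tr$minute > 5 & tr$minute <= duration
  if (any(chk) && !all(is.na(hr[chk]))) {
    inband <- mean(abs(hr[chk] - hr_center) <= hr_halfwidth, na.rm = TRUE)
    if (inband < min_band_fraction) {
      ld_stop(sprintf("only %.0f%% of calibration HR within %g +/- %g BPM",
                      100 * inband, hr_center, hr_halfwidth),
              "legdose_calibration_error")
    }
  }
  at <- which(tr$minute == duration)
  if (length(at) != 1) {
    ld_stop(sprintf("no sample at minute %d of the calibration session", duration),
            "legdose_calibration_error")
  }
  dose_prescription(
    participant_id = participant_id %||% NA_character_,
    dose_threshold = tr$delta_t[at],
    calibrated_at = metrics$boundary$start,
    calibration_session_id = metrics$session_id,
    hr_center = hr_center, hr_halfwidth = hr_halfwidth
  )
}

#' Dose progress
#'
#' Current delta-t expressed as percent of the prescribed dose (e.g. 5.25
#' degrees C against a 10.5-degree dose reads 50). Reported progress is
#' capped at 100 once the dose is exceeded.
#'
#' @param current_delta_t Current delta-t value(s), degrees C (>= 0).
#' @param prescription A [dose_prescription()].
#' @return Percent of dose, in \[0, 100\].
#' @export
dose_progress <- function(current_delta_t, prescription) {
  if (any(!is.finite(current_delta_t)) || any(current_delta_t < 0)) {
    ld_stop("`current_delta_t` must be finite and >= 0")
  }
  pmin(100, 100 * current_delta_t / prescription$dose_threshold)
}

#' Detect dose-completion notification events
#'
#' Scans a (typically week-long) recording and emits one notification per
#' participant per calendar day: the first minute at which any session's
#' delta-t reaches the dose threshold (inclusive `>=`). Later crossings on
#' the same day are debounced. Events stand in for the automatic e-mails of
#' the deployed system and are returned chronologically ordered.
#'
#' @param x A [simulate_week()] result, or a [telemetry_series()] combined
#'   with `sessions`.
#' @param prescription A [dose_prescription()].
#' @param sessions Session list (entries with a `boundary`) when `x` is a
#'   plain series.
#' @return A data frame of class `notification_log` with columns
#'   `participant_id`, `timestamp`, `day` (Date), `dose_threshold_c`.
#' @export
detect_dose_events <- function(x, prescription, sessions = NULL) {
  if (inherits(x, "legdose_week")) {
    series <- x$series
    sessions <- x$sessions
  } else {
    series <- x
    sessions <- sessions %||% list()
  }
  crossings <- as.POSIXct(character(), tz = "UTC")
  for (s in sessions) {
    tr <- compute_delta_t(series, s$boundary)
    hit <- tr$minute > 0 & tr$delta_t >= prescription$dose_threshold
    if (any(hit)) crossings <- c(crossings, tr$timestamp[hit])
  }
  if (length(crossings) == 0) {
    return(empty_notification_log())
  }
  day <- as.Date(crossings, tz = "UTC")
  first <- tapply(as.numeric(crossings), as.character(day), min)
  ts <- as.POSIXct(as.numeric(first), origin = "1970-01-01", tz = "UTC")
  ord <- order(ts)
  out <- data.frame(
    participant_id = prescription$participant_id,
    timestamp = ts[ord],
    day = as.Date(names(first)[ord]),
    dose_threshold_c = prescription$dose_threshold
  )
  class(out) <- c("notification_log", "data.frame")
  out
}

empty_notification_log <- function() {
  out <- data.frame(participant_id = character(),
                    timestamp = as.POSIXct(character(), tz = "UTC"),
                    day = as.Date(character()),
                    dose_threshold_c = numeric())
  class(out) <- c("notification_log", "data.frame")
  out
}

#' Detect uncompleted MICT bouts
#'
#' Retrospective analysis of a week of session metrics: MICT-classified
#' sessions whose peak delta-t stayed below the dose threshold are flagged as
#' uncompleted. Non-MICT (e.g. opportunistic) sessions below threshold are
#' not flagged.
#'
#' @param metrics_list List of [analyze_session()] results.
#' @param prescription A [dose_prescription()].
#' @return A list with `count` and `session_ids`.
#' @export
detect_incomplete_bouts <- function(metrics_list, prescription) {
  flagged <- vapply(metrics_list, function(mx) {
    peak <- if (nrow(mx$bouts) > 0) max(mx$bouts$peak_delta_t) else
      max(0, mx$delta_t$delta_t)
    identical(mx$regimen, "MICT") && peak < prescription$dose_threshold
  }, logical(1))
  list(count = sum(flagged),
       session_ids = vapply(metrics_list[flagged],
                            function(mx) as.character(mx$session_id), ""))
}

#' Weekly adherence report
#'
#' Turns a week of notification events into the tick/cross day flags and the
#' compliance verdict: taking the daily dose on 5 or more days of the week is
#' "good" adherence.
#'
#' @param events A `notification_log` (all events must fall within the week).
#' @param week_start Date of day 1.
#' @param participant_id Participant the report is for (defaults to the id in
#'   `events`).
#' @param incomplete_bouts Count of uncompleted MICT bouts to carry in the
#'   report (see [detect_incomplete_bouts()]).
#' @return An object of class `adherence_report` with `day_flags` (7
#'   logicals), `dose_days`, `compliant`, `incomplete_bouts`.
#' @export
weekly_adherence <- function(events, week_start, participant_id = NULL,
                             incomplete_bouts = 0) {
  week_start <- as.Date(week_start)
  pid <- participant_id %||%
    (if (nrow(events) > 0) events$participant_id[1] else NA_character_)
  flags <- rep(FALSE, 7)
  if (nrow(events) > 0) {
    idx <- as.integer(events$day - week_start) + 1L
    if (any(idx < 1 | idx > 7)) {
      ld_stop("event outside the report week", "legdose_range_error")
    }
    flags[unique(idx)] <- TRUE
  }
  structure(list(participant_id = pid, week_start = week_start,
                 day_flags = flags, dose_days = sum(flags),
                 compliant = sum(flags) >= 5,
                 incomplete_bouts = incomplete_bouts),
            class = "adherence_report")
}

#' @export
print.adherence_report <- function(x, ...) {
  cat(sprintf("<adherence_report> %s, week of %s: [%s] %d dose day(s), %s\n",
              x$participant_id, format(x$week_start),
              paste(ifelse(x$day_flags, "x", "."), collapse = " "),
              x$dose_days,
              if (x$compliant) "compliant" else "noncompliant"))
  invisible(x)
}

#' Cohort adherence table
#'
#' Supervisor view over many participants: one row per participant-week with
#' the 7 tick/cross day flags (`x` = dose taken, `.` = missed), the dose-day
#' count and the compliance verdict, plus a summary count of compliant
#' participants.
#'
#' @param reports List of [weekly_adherence()] reports (one per
#'   participant-week; duplicates are an error).
#' @return A data frame of class `cohort_report` with attribute
#'   `n_compliant`.
#' @export
cohort_report <- function(reports) {
  if (length(reports) == 0) {
    out <- data.frame(participant_id = character(), week_start = as.Date(character()),
                      d1 = character(), d2 = character(), d3 = character(),
                      d4 = character(), d5 = character(), d6 = character(),
                      d7 = character(), dose_days = integer(),
                      compliant = logical())
    attr(out, "n_compliant") <- 0L
    class(out) <- c("cohort_report", "data.frame")
    return(out)
  }
  keys <- vapply(reports, function(r) {
    paste(r$participant_id, format(r$week_start))
  }, "")
  if (anyDuplicated(keys)) {
    ld_stop("duplicate participant-week in cohort report")
  }
  rows <- lapply(reports, function(r) {
    flags <- ifelse(r$day_flags, "x", ".")
    df <- data.frame(participant_id = r$participant_id,
                     week_start = r$week_start)
    for (i in 1:7) df[[paste0("d", i)]] <- flags[i]
    df$dose_days <- r$dose_days
    df$compliant <- r$compliant
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_compliant") <- sum(out$compliant)
  class(out) <- c("cohort_report", "data.frame")
  out
}

#' Format a cohort report as a plain-text tick/cross table
#'
#' @param report A [cohort_report()].
#' @return Character vector of table lines (ASCII only).
#' @export
format_cohort_table <- function(report) {
  header <- sprintf("%-12s %s %s %s %s %s %s %s  %-9s %s",
                    "participant", "D1", "D2", "D3", "D4", "D5", "D6", "D7",
                    "dose_days", "compliant")
  lines <- vapply(seq_len(nrow(report)), function(i) {
    sprintf("%-12s %2s %2s %2s %2s %2s %2s %2s  %9d %s",
            report$participant_id[i],
            report$d1[i], report$d2[i], report$d3[i], report$d4[i],
            report$d5[i], report$d6[i], report$d7[i],
            report$dose_days[i],
            if (report$compliant[i]) "yes" else "no")
  }, "")
  summary <- sprintf("%d of %d participants compliant (>= 5 dose days)",
                     attr(report, "n_compliant"), nrow(report))
  c(header, lines, summary)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(paste(format_cohort_table(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Cohort-mean dose prescriptions
#'
#' In the home-training deployment a single cohort-mean dose was prescribed
#' to all participants; this helper converts a set of personal prescriptions
#' into that mode. `mode = "personal"` returns the prescriptions unchanged.
#'
#' @param prescriptions List of [dose_prescription()] objects.
#' @param mode `"personal"` or `"cohort-mean"`.
#' @return List of prescriptions.
#' @export
apply_dose_mode <- function(prescriptions, mode = c("personal", "cohort-mean")) {
  mode <- match.arg(mode)
  if (mode == "personal" || length(prescriptions) == 0) return(prescriptions)
  m <- mean(vapply(prescriptions, function(p) p$dose_threshold, 0))
  lapply(prescriptions, function(p) {
    p$dose_threshold <- m
    p
  })
}
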