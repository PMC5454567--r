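# Telemetry and config I/O: the on-disk formats every other module works from.
#
# CSV dialect (fixed): comma separator, dot decimal, header row
#   timestamp,temperature_c,heart_rate_bpm,spo2_pct,systolic_mmhg,diastolic_mmhg
# ISO-8601 local timestamps without timezone suffix, one row per minute.
# Missing minutes are absent rows; missing optional channels are empty cells.

SAMPLE_COLS <- c("timestamp", "temperature_c", "heart_rate_bpm",
                 "spo2_pct", "systolic_mmhg", "diastolic_mmhg")

#' Construct a telemetry series
#'
#' A `telemetry_series` is the in-memory model of one participant's
#' minute-resolution recording: device temperature (degrees C), heart rate
#' (BPM) and optional SpO2 (%) and blood pressure (mmHg) channels.
#'
#' Invariants enforced: strictly increasing timestamps (no duplicates), finite
#' temperature, heart rate in \[20, 250\] and SpO2 in \[50, 100\] when present.
#'
#' @param participant_id Opaque participant identifier.
#' @param samples Data frame with a `timestamp` (POSIXct) and `temperature_c`
#'   column; optional `heart_rate_bpm`, `spo2_pct`, `systolic_mmhg`,
#'   `diastolic_mmhg` columns are filled with `NA` when absent.
#' @param sampling_interval Nominal sampling interval in minutes (default 1).
#' @param zeroed `TRUE` when temperatures are session-relative (the device was
#'   zeroed at session start), `FALSE` for raw absolute traces.
#' @return An object of class `telemetry_series`.
#' @export
telemetry_series <- function(participant_id, samples, sampling_interval = 1,
                             zeroed = TRUE) {
  if (!is.data.frame(samples)) {
    ld_stop("`samples` must be a data frame")
  }
  if (is.null(samples$timestamp) || is.null(samples$temperature_c)) {
    ld_stop("`samples` needs `timestamp` and `temperature_c` columns")
  }
  samples$timestamp <- as.POSIXct(samples$timestamp, tz = "UTC")
  for (col in SAMPLE_COLS[-(1:2)]) {
    if (is.null(samples[[col]])) samples[[col]] <- rep(NA_real_, nrow(samples))
    samples[[col]] <- as.numeric(samples[[col]])
  }
  samples <- samples[SAMPLE_COLS]
  rownames(samples) <- NULL
  bad <- sample_violations(samples)
  if (any(bad)) {
    ld_stop(sprintf("%d sample row(s) violate telemetry invariants", sum(bad)))
  }
  assert_flag(zeroed, "zeroed")
  structure(
    list(participant_id = as.character(participant_id)[1],
         samples = samples,
         sampling_interval = sampling_interval,
         zeroed = isTRUE(zeroed)),
    class = "telemetry_series"
  )
}

# Row-level invariant violations: NA/duplicate/non-increasing timestamp,
# non-finite temperature, out-of-range optional channels.
sample_violations <- function(samples) {
  ts <- samples$timestamp
  bad <- is.na(ts) | !is.finite(samples$temperature_c)
  hr <- samples$heart_rate_bpm
  bad <- bad | (!is.na(hr) & (hr < 20 | hr > 250))
  sp <- samples$spo2_pct
  bad <- bad | (!is.na(sp) & (sp < 50 | sp > 100))
  # a row duplicating (or preceding) the latest valid timestamp is a violation
  dup <- duplicated(ts) | c(FALSE, diff(as.numeric(ts)) < 0)
  bad | dup
}

#' @export
print.telemetry_series <- function(x, ...) {
  n <- nrow(x$samples)
  rng <- if (n > 0) paste(format_ts(range(x$samples$timestamp)), collapse = " .. ") else "empty"
  cat(sprintf("<telemetry_series> participant %s: %d samples (%s), %s\n",
              x$participant_id, n, rng,
              if (x$zeroed) "session-relative (zeroed)" else "absolute"))
  invisible(x)
}

#' Read a telemetry CSV file
#'
#' Parses the documented telemetry CSV dialect. In strict mode any row that
#' violates the sample invariants (duplicate timestamp, non-finite
#' temperature, out-of-range heart rate or SpO2) is an error; in lenient mode
#' such rows are dropped and the number of drops is reported via `message()`.
#'
#' @param path Path to a telemetry CSV file.
#' @param strict Reject invalid rows (`TRUE`) or drop them with a logged
#'   count (`FALSE`, default).
#' @param participant_id Participant id to attach; defaults to the file name
#'   without extension (the id is not part of the CSV dialect).
#' @param zeroed Whether the stored temperatures are session-relative.
#' @return A [telemetry_series()].
#' @export
read_telemetry <- function(path, strict = FALSE, participant_id = NULL,
                           zeroed = TRUE) {
  if (!file.exists(path)) {
    ld_stop(sprintf("telemetry file not found: %s", path), "legdose_io_error")
  }
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) ld_stop(sprintf("cannot parse CSV %s: %s",
                                        path, conditionMessage(e)),
                                "legdose_format_error")
  )
  nm <- names(raw)
  if (!all(c("timestamp", "temperature_c") %in% nm) || !all(nm %in% SAMPLE_COLS)) {
    ld_stop(sprintf("malformed telemetry header in %s: %s",
                    path, paste(nm, collapse = ",")),
            "legdose_format_error")
  }
  samples <- data.frame(timestamp = parse_ts(raw$timestamp))
  for (col in SAMPLE_COLS[-1]) {
    vals <- if (col %in% nm) raw[[col]] else rep("", nrow(raw))
    vals[vals == ""] <- NA
    samples[[col]] <- suppressWarnings(as.numeric(vals))
  }
  bad <- sample_violations(samples)
  if (any(bad)) {
    if (strict) {
      ld_stop(sprintf("%d row(s) in %s violate telemetry invariants",
                      sum(bad), path))
    }
    message(sprintf("read_telemetry: dropped %d invalid row(s) from %s",
                    sum(bad), path))
    samples <- samples[!bad, , drop = FALSE]
  }
  pid <- participant_id %||% sub("\\.[^.]*$", "", basename(path))
  telemetry_series(pid, samples, zeroed = zeroed)
}

#' Write a telemetry series to CSV
#'
#' Lossless counterpart of [read_telemetry()]: all present channels and
#' timestamps round-trip exactly, and re-writing a read series produces a
#' byte-identical file.
#'
#' @param series A [telemetry_series()].
#' @param path Destination file path.
#' @return The file path, invisibly.
#' @export
write_telemetry <- function(series, path) {
  if (!inherits(series, "telemetry_series")) {
    ld_stop("`series` must be a telemetry_series")
  }
  s <- series$samples
  out <- data.frame(timestamp = format_ts(s$timestamp))
  for (col in SAMPLE_COLS[-1]) out[[col]] <- fmt_num(s[[col]])
  con <- tryCatch(file(path, "w"), error = function(e) {
    ld_stop(sprintf("cannot write %s: %s", path, conditionMessage(e)),
            "legdose_io_error")
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Session boundary
#'
#' Marks one training session inside a longer recording. The device is zeroed
#' before each session, so `zero_reference` must equal the temperature of the
#' first in-session sample; [compute_delta_t()] subtracts it.
#'
#' @param start,end Session start/end timestamps (`start < end`).
#' @param zero_reference Temperature reading at session start, degrees C.
#' @return An object of class `session_boundary`.
#' @export
session_boundary <- function(start, end, zero_reference = 0) {
  start <- as_ts(start, "start")
  end <- as_ts(end, "end")
  if (!(start < end)) ld_stop("session boundary requires start < end")
  assert_num(zero_reference, "zero_reference")
  structure(list(start = start, end = end, zero_reference = zero_reference),
            class = "session_boundary")
}

#' Read/write session boundary tables
#'
#' Sessions are stored as a small CSV with columns
#' `session_id,kind,start,end,zero_reference_c` (`kind` may be empty when the
#' protocol is unknown).
#'
#' @param path CSV file path.
#' @return `read_sessions()`: a list of entries, each with `session_id`,
#'   `kind` and a [session_boundary()]. `write_sessions()`: the path,
#'   invisibly.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) {
    ld_stop(sprintf("session file not found: %s", path), "legdose_io_error")
  }
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("session_id", "start", "end", "zero_reference_c")
  if (!all(need %in% names(raw))) {
    ld_stop(sprintf("malformed session header in %s", path),
            "legdose_format_error")
  }
  lapply(seq_len(nrow(raw)), function(i) {
    list(session_id = raw$session_id[i],
         kind = if ("kind" %in% names(raw)) raw$kind[i] else NA_character_,
         boundary = session_boundary(parse_ts(raw$start[i]),
                                     parse_ts(raw$end[i]),
                                     as.numeric(raw$zero_reference_c[i])))
  })
}

#' @param sessions List of session entries (as returned by [read_sessions()]
#'   or found in a [simulate_week()] result).
#' @rdname read_sessions
#' @export
write_sessions <- function(sessions, path) {
  df <- data.frame(
    session_id = vapply(sessions, function(s) s$session_id, ""),
    kind = vapply(sessions, function(s) as.character(s$kind %||% NA), ""),
    start = vapply(sessions, function(s) format_ts(s$boundary$start), ""),
    end = vapply(sessions, function(s) format_ts(s$boundary$end), ""),
    zero_reference_c = fmt_num(vapply(sessions,
                                      function(s) s$boundary$zero_reference, 0))
  )
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a participant profile
#'
#' Profiles are flat JSON files. Only `participant_id` is required; all other
#' keys default to the [participant_model()] defaults. Recognized keys:
#' `heat_coefficient`, `cooling_rate`, `ambient_offset`, `hr_rest`,
#' `hr_gain`, `hr_tau`, `hr_noise_sd`, `spo2_baseline`, `bp_systolic`,
#' `bp_diastolic`, `bp_exercise_slope`.
#'
#' @param path Path to a profile JSON file.
#' @return A [participant_model()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) {
    ld_stop(sprintf("profile not found: %s", path), "legdose_io_error")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("participant_id", "heat_coefficient", "cooling_rate",
             "ambient_offset", "hr_rest", "hr_gain", "hr_tau", "hr_noise_sd",
             "spo2_baseline", "bp_systolic", "bp_diastolic",
             "bp_exercise_slope")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    warning(sprintf("read_profile: ignoring unknown key(s): %s",
                    paste(extra, collapse = ", ")))
  }
  if (is.null(cfg$participant_id)) {
    ld_stop(sprintf("profile %s is missing `participant_id`", path))
  }
  participant_model(
    participant_id = cfg$participant_id,
    thermal = thermal_params(
      heat_coefficient = cfg$heat_coefficient %||% formals(thermal_params)$heat_coefficient,
      cooling_rate = cfg$cooling_rate %||% formals(thermal_params)$cooling_rate,
      ambient_offset = cfg$ambient_offset %||% formals(thermal_params)$ambient_offset
    ),
    hr = hr_params(
      hr_rest = cfg$hr_rest %||% formals(hr_params)$hr_rest,
      hr_gain = cfg$hr_gain %||% formals(hr_params)$hr_gain,
      tau = cfg$hr_tau %||% formals(hr_params)$tau,
      hr_noise_sd = cfg$hr_noise_sd %||% formals(hr_params)$hr_noise_sd
    ),
    spo2_baseline = cfg$spo2_baseline %||% formals(participant_model)$spo2_baseline,
    bp_systolic = cfg$bp_systolic %||% formals(participant_model)$bp_systolic,
    bp_diastolic = cfg$bp_diastolic %||% formals(participant_model)$bp_diastolic,
    bp_exercise_slope = cfg$bp_exercise_slope %||% formals(participant_model)$bp_exercise_slope
  )
}

#' Write a participant profile
#'
#' @param participant A [participant_model()].
#' @param path Destination JSON path.
#' @return The path, invisibly.
#' @export
write_profile <- function(participant, path) {
  p <- participant
  jsonlite::write_json(
    list(participant_id = p$participant_id,
         heat_coefficient = p$thermal$heat_coefficient,
         cooling_rate = p$thermal$cooling_rate,
         ambient_offset = p$thermal$ambient_offset,
         hr_rest = p$hr$hr_rest,
         hr_gain = p$hr$hr_gain,
         hr_tau = p$hr$tau,
         hr_noise_sd = p$hr$hr_noise_sd,
         spo2_baseline = p$spo2_baseline,
         bp_systolic = p$bp_systolic,
         bp_diastolic = p$bp_diastolic,
         bp_exercise_slope = p$bp_exercise_slope),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
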