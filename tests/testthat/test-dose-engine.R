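# dose_engine: calibration, progress, events with debouncing, incomplete
# bouts, weekly and cohort adherence.

test_that("calibrate_dose matches the closed form and enforces preconditions", {
  p <- default_pt()
  rx <- calibrated_rx(p)
  expect_s3_class(rx, "dose_prescription")
  expect_lt(abs(rx$dose_threshold - predicted_dose(p)) / predicted_dose(p), 0.05)

  # noise-free calibration is within 2% of (k Pbar / lambda)(1 - e^{-30 lambda})
  cal0 <- simulate_protocol(protocol_spec("dosed_mict"), p, seed = 2,
                            noise = FALSE)
  mx0 <- analyze_session(cal0$series, cal0$boundary, session_id = "CAL")
  rx0 <- calibrate_dose(mx0, participant_id = "P01")
  expect_lt(abs(rx0$dose_threshold - predicted_dose(p)) / predicted_dose(p), 0.02)

  # the 10.5-degree participant gets the 10.5-degree dose
  p105 <- default_pt(thermal = thermal_params(k_for_dose(10.5), 0.05))
  cal105 <- simulate_protocol(protocol_spec("dosed_mict"), p105, seed = 2,
                              noise = FALSE)
  rx105 <- calibrate_dose(analyze_session(cal105$series, cal105$boundary),
                          participant_id = "P105")
  expect_lt(abs(rx105$dose_threshold - 10.5) / 10.5, 0.02)

  # shorter than 30 minutes -> calibration error
  short <- simulate_week(list(list(day = 1, spec = protocol_spec("mict", duration = 29))),
                         p, seed = 3)
  mshort <- analyze_session(short$series, short$sessions[[1]]$boundary)
  expect_error(calibrate_dose(mshort), class = "legdose_calibration_error")

  # non-MICT session -> calibration error
  hi <- sim_session("hiit_wingate", seed = 4)
  mhi <- analyze_session(hi$series, hi$boundary)
  expect_error(calibrate_dose(mhi), class = "legdose_calibration_error")
})

test_that("dose progress arithmetic matches the digital interface", {
  rx <- dose_prescription("P01", 10.5)
  expect_equal(dose_progress(5.25, rx), 50)
  expect_equal(dose_progress(0, rx), 0)
  expect_equal(dose_progress(10.5, rx), 100)
  expect_equal(dose_progress(12.3, rx), 100)  # capped once exceeded
  expect_error(dose_progress(-1, rx), class = "legdose_validation_error")
})

test_that("dose events fire once per day at the first crossing", {
  p <- default_pt()
  rx <- calibrated_rx(p)
  week <- simulate_week(dose_schedule(c(1, 3, 4, 5, 7)), p, seed = 21)
  ev <- detect_dose_events(week, rx)
  expect_equal(nrow(ev), 5L)
  expect_equal(ev$day, week$week_start + c(0, 2, 3, 4, 6))
  expect_true(!is.unsorted(ev$timestamp))

  # debounce: two completed sessions on one day emit a single event
  two <- simulate_week(list(
    list(day = 2, spec = protocol_spec("mict", duration = 45), start_hour = 9),
    list(day = 2, spec = protocol_spec("mict", duration = 45), start_hour = 15)
  ), p, seed = 9)
  expect_equal(nrow(detect_dose_events(two, rx)), 1L)

  # nothing crosses an unreachably high threshold
  expect_equal(nrow(detect_dose_events(week, dose_prescription("P01", 50))), 0L)

  # monotonicity: lowering the threshold never loses dose days
  lower <- detect_dose_events(week, dose_prescription("P01",
                                                      rx$dose_threshold * 0.5))
  expect_gte(nrow(lower), nrow(ev))
})

test_that("incomplete MICT bouts are flagged; other regimens are not", {
  p <- default_pt()
  rx <- calibrated_rx(p)
  week <- simulate_week(c(dose_schedule(c(1, 3)),
                          list(list(day = 5, spec = protocol_spec("mict", duration = 15)),
                               list(day = 6, spec = protocol_spec("desk_opportunistic",
                                                                  duration = 90)))),
                        p, seed = 31)
  mets <- lapply(week$sessions, function(s) {
    analyze_session(week$series, s$boundary, session_id = s$session_id)
  })
  inc <- detect_incomplete_bouts(mets, rx)
  truncated <- which(vapply(week$sessions, function(s) {
    s$kind == "mict" &&
      as.numeric(difftime(s$boundary$end, s$boundary$start, units = "mins")) == 15
  }, TRUE))
  expect_equal(inc$count, 1L)
  expect_equal(inc$session_ids, week$sessions[[truncated]]$session_id)

  complete <- detect_incomplete_bouts(mets[-truncated], rx)
  # opportunistic session stays unflagged even though it peaks below threshold
  expect_equal(complete$count, 0L)
})

test_that("weekly adherence implements the 5-day rule", {
  ws <- as.Date("2015-06-01")
  mk_events <- function(days) {
    out <- data.frame(participant_id = "P01",
                      timestamp = as_ts(ws) + (days - 1) * 86400 + 9.5 * 3600,
                      day = ws + days - 1, dose_threshold_c = 7.8)
    class(out) <- c("notification_log", "data.frame")
    out
  }
  r5 <- weekly_adherence(mk_events(c(1, 3, 4, 5, 7)), ws)
  expect_equal(r5$day_flags, c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(r5$dose_days, 5L)
  expect_true(r5$compliant)

  expect_false(weekly_adherence(mk_events(c(2, 3, 5, 6)), ws)$compliant)
  r7 <- weekly_adherence(mk_events(1:7), ws)
  expect_equal(r7$dose_days, 7L)
  expect_true(r7$compliant)
  expect_true(weekly_adherence(empty_notification_log(), ws,
                               "P01")$dose_days == 0)

  expect_error(weekly_adherence(mk_events(8), ws), class = "legdose_range_error")
})

test_that("dose_days equals a brute-force recount of distinct crossing dates", {
  p <- default_pt()
  rx <- calibrated_rx(p)
  for (s in 1:10) {
    days <- sort(sample(1:7, sample(0:7, 1)))
    week <- simulate_week(dose_schedule(days), p, seed = 700 + s)
    ev <- detect_dose_events(week, rx)
    rep <- weekly_adherence(ev, week$week_start, "P01")
    # brute force: scan every minute of the raw telemetry
    hits <- Reduce(rbind, lapply(week$sessions, function(ss) {
      tr <- compute_delta_t(week$series, ss$boundary)
      tr[tr$minute > 0 & tr$delta_t >= rx$dose_threshold, , drop = FALSE]
    }), accumulate = FALSE)
    brute <- if (is.null(hits) || nrow(hits) == 0) 0L else
      length(unique(as.Date(hits$timestamp, tz = "UTC")))
    expect_equal(rep$dose_days, brute)
  }
})

test_that("cohort reports aggregate verdicts and reject duplicates", {
  ws <- as.Date("2015-06-01")
  mk_rep <- function(pid, days) {
    ev <- data.frame(participant_id = pid,
                     timestamp = as_ts(ws) + (days - 1) * 86400 + 34200,
                     day = ws + days - 1, dose_threshold_c = 7.8)
    class(ev) <- c("notification_log", "data.frame")
    weekly_adherence(ev, ws, pid)
  }
  reps <- list(mk_rep("P01", c(1, 3, 4, 5, 7)),
               mk_rep("P02", c(2, 3, 4, 6, 7)),
               mk_rep("P03", c(1, 2, 3, 5, 6, 7)))
  tab <- cohort_report(reps)
  expect_equal(tab$dose_days, c(5L, 5L, 6L))
  expect_true(all(tab$compliant))
  expect_equal(attr(tab, "n_compliant"), 3L)
  expect_match(tail(format_cohort_table(tab), 1), "3 of 3")

  empty <- cohort_report(list())
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_compliant"), 0L)

  expect_error(cohort_report(list(reps[[1]], reps[[1]])),
               class = "legdose_validation_error")
})

test_that("cohort-mean dose mode prescribes the mean to everyone", {
  rxs <- list(dose_prescription("P01", 6), dose_prescription("P02", 9))
  out <- apply_dose_mode(rxs, "cohort-mean")
  expect_equal(vapply(out, function(p) p$dose_threshold, 0), c(7.5, 7.5))
  expect_identical(apply_dose_mode(rxs, "personal"), rxs)
})
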