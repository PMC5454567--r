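# Session analysis: delta-t traces, active-bout segmentation, regimen
# classification, mobilization minutes, and thermal-model inversion.

#' Compute the session-relative temperature trace
#'
#' Subtracts the session's zero reference (the temperature of the first
#' in-session sample -- the device is zeroed before each session) from every
#' in-session temperature. The first value is exactly 0. Missing minutes stay
#' missing: no interpolation.
#'
#' @param series A [telemetry_series()].
#' @param boundary A [session_boundary()] lying inside the series time range.
#' @return A data frame of class `delta_t_trace` with columns `timestamp`,
#'   `minute` (offset from session start) and `delta_t` (degrees C), plus the
#'   session's `heart_rate_bpm` channel for downstream use.
#' @export
compute_delta_t <- function(series, boundary) {
  ts <- series$samples$timestamp
  if (length(ts) == 0 || boundary$start < min(ts) || boundary$end > max(ts)) {
    ld_stop("session boundary lies outside the series time range",
            "legdose_range_error")
  }
  keep <- ts >= boundary$start & ts <= boundary$end
  sub <- series$samples[keep, , drop = FALSE]
  ref <- sub$temperature_c[1]
  out <- data.frame(
    timestamp = sub$timestamp,
    minute = as.numeric(difftime(sub$timestamp, boundary$start, units = "mins")),
    delta_t = sub$temperature_c - ref,
    heart_rate_bpm = sub$heart_rate_bpm
  )
  class(out) <- c("delta_t_trace", class(out))
  out
}

as_delta_df <- function(delta_t) {
  if (is.data.frame(delta_t)) {
    if (is.null(delta_t$delta_t)) ld_stop("`delta_t` data frame needs a `delta_t` column")
    d <- delta_t$delta_t
    m <- delta_t$minute %||% (seq_along(d) - 1)
    ts <- delta_t$timestamp %||% NULL
  } else {
    d <- as.numeric(delta_t)
    m <- seq_along(d) - 1
    ts <- NULL
  }
  list(d = d, m = m, ts = ts)
}

#' Segment active training bouts from a delta-t trace
#'
#' A minute counts as active when any of three conditions holds:
#' \enumerate{
#'   \item the centered finite-difference slope is at least `slope_threshold`;
#'   \item the trace is still rising after 3-point moving-average smoothing
#'     (smoothed slope above `rise_threshold`);
#'   \item the heat-input rate `q(t) = slope(t) + cooling_rate * delta_t(t)`
#'     -- the deviation from free Newtonian cooling, i.e. `k * P(t)` under
#'     the thermal model -- averaged over 3 minutes is at least `heat_min`.
#'     This catches continued exercise near the thermal steady state, where
#'     the raw slope goes to zero (or negative) although work input
#'     continues.
#' }
#' The minute mask is despeckled with a 3-point majority vote and run edges
#' are refined with the 1-minute heat-input rate, so bout boundaries align
#' with the power steps to about one minute. Active runs separated by gaps
#' shorter than `merge_gap` minutes are merged; merged runs with fewer than
#' `min_len` active minutes are discarded. Bouts are ordered and
#' non-overlapping.
#'
#' @param delta_t A `delta_t_trace` from [compute_delta_t()] or a plain
#'   numeric delta-t series at 1-minute spacing.
#' @param slope_threshold Minimum active slope, degrees C per minute
#'   (default 0.05).
#' @param merge_gap Merge active runs closer than this, minutes (default 5).
#' @param min_len Discard bouts with fewer active minutes than this
#'   (default 3).
#' @param rise_threshold Smoothed-slope floor for the "still rising" clause,
#'   degrees C per minute (default 0.02; guards against calling flat sensor
#'   noise a rise).
#' @param cooling_rate Device cooling rate used by the heat-input clause,
#'   per minute (default 0.05, the default device).
#' @param heat_min Minimum heat-input rate counted as training, degrees C
#'   per minute (default 0.05: half the rate of the lightest simulated
#'   opportunistic pedalling on the default device).
#' @return A data frame of class `bout_table` with one row per bout
#'   (`start`, `end`, `peak_delta_t`, `active_minutes`, `mean_hr`) and an
#'   `active_mask` attribute flagging the active samples of the input trace.
#' @export
detect_bouts <- function(delta_t, slope_threshold = 0.05, merge_gap = 5,
                         min_len = 3, rise_threshold = 0.02,
                         cooling_rate = 0.05, heat_min = 0.05) {
  assert_num(slope_threshold, "slope_threshold", lower = 1e-12)
  assert_num(merge_gap, "merge_gap", lower = 1e-12)
  assert_num(min_len, "min_len", lower = 1e-12)
  x <- as_delta_df(delta_t)
  d <- x$d
  m <- x$m
  n <- length(d)
  if (n == 0) ld_stop("`delta_t` series is empty")
  empty <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      peak_delta_t = numeric(0), active_minutes = integer(0),
                      mean_hr = numeric(0))
  if (n < 3) {
    return(bout_table(empty, rep(FALSE, n), x, numeric(n)))
  }
  s_ctr <- slope_centered(d, m)
  s_bwd <- slope_backward(d, m)
  s_sm <- slope_centered(smooth3(d), m)
  # heat-input rate (k*P under the model): 1-minute and 3-minute-pooled
  q1 <- s_bwd + cooling_rate * pmax(d, 0)
  q3 <- smooth3(q1)
  active <- s_ctr >= slope_threshold | s_sm > rise_threshold | q3 >= heat_min
  # 3-point majority vote despeckles isolated flips
  if (n >= 3) {
    votes <- active + c(active[-1], active[n]) + c(active[1], active[-n])
    active <- votes >= 2
  }
  # refine run edges (+/- 2 min) with the sharper 1-minute heat rate
  active <- refine_edges(active, q1, heat_min)
  # punch short breaks the pooled detector bridged: a 1-3 minute window whose
  # own heat input stays below half the threshold is a break, even when its
  # active neighbours dominate the pooled rate
  active <- punch_short_breaks(active, q1, heat_min)
  # run validation: the total heat input of a candidate run must clear the
  # sensor-noise floor (estimated robustly from the quiet minutes), so that
  # correlated noise exceedances inside breaks do not become activity
  noise_sd <- stats::mad(q1[!active])
  if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- 1e-6
  active <- validate_runs(active, q1, heat_min, noise_sd)
  # runs of active minutes
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- m[runs$start[i]] - m[merged$end[nrow(merged)]] - 1
      if (gap < merge_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  if (nrow(runs) == 0) {
    return(bout_table(empty, rep(FALSE, n), x, s_sm))
  }
  keep_mask <- rep(FALSE, n)
  rows <- list()
  for (i in seq_len(nrow(runs))) {
    span <- runs$start[i]:runs$end[i]
    act <- span[active[span]]
    if (length(act) < min_len) next
    keep_mask[act] <- TRUE
    hr <- if (!is.null(x$ts)) delta_t$heart_rate_bpm[span] else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      start = if (!is.null(x$ts)) x$ts[span[1]] else as.POSIXct(NA),
      end = if (!is.null(x$ts)) x$ts[span[length(span)]] else as.POSIXct(NA),
      first_index = span[1], last_index = span[length(span)],
      peak_delta_t = max(0, max(d[span])),
      active_minutes = length(act),
      mean_hr = if (all(is.na(hr))) NA_real_ else mean(hr, na.rm = TRUE)
    )
  }
  bouts <- if (length(rows) > 0) do.call(rbind, rows) else
    cbind(empty, data.frame(first_index = integer(0), last_index = integer(0)))
  bout_table(bouts, keep_mask, x, s_sm)
}

# Shift the edges of each active run by up to 2 minutes so they agree with
# the 1-minute heat-input rate (full-signal at a power step, so sharper than
# the pooled detector that found the run).
refine_edges <- function(active, q1, heat_min) {
  n <- length(active)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- rep(FALSE, n)
  prev_end <- 0L
  for (j in which(r$values)) {
    s <- starts[j]
    e <- ends[j]
    for (step in 1:2) {
      if (s - 1L > prev_end && q1[s - 1L] >= heat_min) s <- s - 1L
      else if (s < e && q1[s] < heat_min) s <- s + 1L
      else break
    }
    for (step in 1:2) {
      if (e + 1L <= n && q1[e + 1L] >= heat_min) e <- e + 1L
      else if (e > s && q1[e] < heat_min) e <- e - 1L
      else break
    }
    if (s <= e) out[s:e] <- TRUE
    prev_end <- e
  }
  out
}

# Mark 1-3 minute windows inside active runs as breaks when their mean
# 1-minute heat rate stays below half the activity threshold.
punch_short_breaks <- function(active, q1, heat_min) {
  n <- length(active)
  out <- active
  for (L in 3:1) {
    if (n < L) next
    wmean <- if (L == 1) q1 else
      as.numeric(stats::filter(q1, rep(1 / L, L), sides = 1))
    # wmean[i] = mean(q1[(i-L+1):i]); window must lie inside an active run
    for (i in L:n) {
      span <- (i - L + 1L):i
      if (all(active[span]) && !is.na(wmean[i]) && wmean[i] < 0.5 * heat_min) {
        out[span] <- FALSE
      }
    }
  }
  out
}

# Keep a candidate run only if its cumulative heat input is both practically
# (mean >= 0.7 * heat_min) and statistically (2.3 sigma) above the noise.
validate_runs <- function(active, q1, heat_min, noise_sd) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- active
  for (j in which(r$values)) {
    span <- starts[j]:ends[j]
    len <- length(span)
    tot <- sum(q1[span])
    if (tot < 0.7 * heat_min * len || tot < 2.3 * noise_sd * sqrt(len)) {
      out[span] <- FALSE
    }
  }
  out
}

bout_table <- function(bouts, mask, x, s_sm) {
  rownames(bouts) <- NULL
  structure(bouts,
            active_mask = mask,
            trace = x,
            class = c("bout_table", "data.frame"))
}

#' Classify the training regimen of one session
#'
#' Deterministic rule-based classifier over the detected bouts and the
#' delta-t trace:
#' \describe{
#'   \item{HIIT}{at least `hiit_min_peaks` alternations between high- and
#'     moderate-slope states inside the dominant bout. Alternations are
#'     counted as peaks of the median-detrended backward slope exceeding
#'     `hiit_amp`, with median peak spacing at most `hiit_max_gap` minutes
#'     (the Wingate-style cycle is 2.5 minutes).}
#'   \item{MICT}{one dominant bout (at least `dominant_share` of all active
#'     minutes), duration 10-120 minutes, essentially no in-bout cooling
#'     minutes, and a low coefficient of variation of the cooling-corrected
#'     active slope. Under the first-order thermal model a constant-power
#'     bout satisfies `slope = k*P - lambda*delta_t`, so the correction is
#'     the goodness of fit (R^2) of `slope ~ delta_t`, which must reach
#'     `r2_cutoff`.}
#'   \item{opportunistic}{anything with multiple bouts, in-bout breaks, or a
#'     low/variable slope.}
#'   \item{unknown}{no rule fires (e.g. a single clean bout shorter than 10
#'     minutes).}
#' }
#'
#' @param bouts A `bout_table` from [detect_bouts()] (must be nonempty).
#' @param delta_t The trace the bouts came from.
#' @param hr Optional per-minute heart rate (unused by the rules; kept so the
#'   interface carries the full session context).
#' @param hiit_min_peaks,hiit_amp,hiit_max_gap HIIT rule knobs (defaults 6
#'   alternations, 0.15 degrees C/min amplitude, 4 minutes spacing).
#' @param r2_cutoff MICT fit cutoff (default 0.75).
#' @param dominant_share Minimum share of active minutes in the dominant
#'   bout for MICT (default 0.8).
#' @param max_cool Maximum tolerated cooling minutes inside a MICT bout
#'   (default 1).
#' @return One of `"MICT"`, `"HIIT"`, `"opportunistic"`, `"unknown"`.
#' @export
classify_regimen <- function(bouts, delta_t, hr = NULL,
                             hiit_min_peaks = 6, hiit_amp = 0.15,
                             hiit_max_gap = 4, r2_cutoff = 0.75,
                             dominant_share = 0.8, max_cool = 1) {
  if (!is.data.frame(bouts) || nrow(bouts) == 0) {
    ld_stop("classify_regimen needs at least one bout")
  }
  x <- as_delta_df(delta_t)
  d <- x$d
  m <- x$m
  dom <- which.max(bouts$active_minutes)
  span <- bouts$first_index[dom]:bouts$last_index[dom]
  ds <- d[span]
  ms <- m[span]
  # --- HIIT: alternation peaks of the detrended backward slope -------------
  sb <- slope_backward(ds, ms)
  base <- stats::runmed(sb, k = min(5, length(sb) - (1 - length(sb) %% 2)))
  det <- sb - base
  high <- det > hiit_amp
  r <- rle(high)
  peak_runs <- which(r$values)
  n_peaks <- length(peak_runs)
  if (n_peaks >= hiit_min_peaks) {
    ends <- cumsum(r$lengths)
    centers <- ms[ends[peak_runs] - r$lengths[peak_runs] / 2 + 0.5]
    if (stats::median(diff(centers)) <= hiit_max_gap) return("HIIT")
  }
  # --- MICT: cooling-corrected slope regularity ----------------------------
  ss <- slope_centered(smooth3(ds), ms)
  n_cool <- sum(ss < -0.05)
  fit_r2 <- if (length(ss) > 2 && stats::var(ss) > 0) {
    summary(stats::lm(ss ~ ds))$r.squared
  } else 1
  share <- bouts$active_minutes[dom] / sum(bouts$active_minutes)
  duration <- ms[length(ms)] - ms[1] + 1
  if (share >= dominant_share && duration >= 10 && duration <= 120 &&
      n_cool <= max_cool && fit_r2 >= r2_cutoff) {
    return("MICT")
  }
  if (nrow(bouts) >= 2 || n_cool >= 2 || fit_r2 < r2_cutoff) {
    return("opportunistic")
  }
  "unknown"
}

#' Invert the thermal model to estimate work output
#'
#' Under the first-order thermal model, power follows from the trace as
#' `P(t) = (delta_t'(t) + lambda * (delta_t(t) - ambient_offset)) / k`.
#' The derivative is a centered finite difference in the interior and
#' one-sided at the edges; estimates are floored at 0 W. Estimates within a
#' minute or two of a power change (and at the trace edges) carry the usual
#' finite-difference transient.
#'
#' @param delta_t Session-relative trace ([compute_delta_t()] output or a
#'   numeric vector at 1-minute spacing).
#' @param params The device's [thermal_params()].
#' @return Per-minute estimated power, watts.
#' @export
estimate_power <- function(delta_t, params) {
  if (!is_scalar_num(params$heat_coefficient) || params$heat_coefficient <= 0) {
    ld_stop("`heat_coefficient` must be > 0")
  }
  x <- as_delta_df(delta_t)
  slope <- slope_centered(x$d, x$m)
  amb <- params$ambient_offset %||% 0
  pmax(0, (slope + params$cooling_rate * (x$d - amb)) / params$heat_coefficient)
}

#' Total mobilization minutes
#'
#' Sum of active minutes across bouts -- the "prolonged leg mobilization"
#' summary for opportunistic training. Invariant to bout ordering and
#' additive over disjoint bout sets.
#'
#' @param bouts A `bout_table` (or any data frame with `active_minutes`).
#' @return Total active minutes (0 for an empty table).
#' @export
mobilization_minutes <- function(bouts) {
  if (is.null(bouts) || NROW(bouts) == 0) return(0)
  sum(bouts$active_minutes)
}

#' Analyze one session end-to-end
#'
#' Convenience wrapper producing the per-session metrics bundle: delta-t
#' trace, bouts, regimen label, mobilization minutes and (when the device
#' parameters are known) the inverted power estimate.
#'
#' @param series A [telemetry_series()].
#' @param boundary The session's [session_boundary()].
#' @param thermal Optional [thermal_params()] enabling [estimate_power()].
#' @param session_id Optional identifier carried into the metrics.
#' @param ... Tuning parameters passed to [detect_bouts()].
#' @return An object of class `session_metrics` with fields `session_id`,
#'   `boundary`, `delta_t`, `bouts`, `regimen`, `mobilization_minutes`,
#'   `est_power`.
#' @export
analyze_session <- function(series, boundary, thermal = NULL,
                            session_id = NA_character_, ...) {
  delta <- compute_delta_t(series, boundary)
  bouts <- detect_bouts(delta, ...)
  regimen <- if (nrow(bouts) > 0) {
    classify_regimen(bouts, delta, hr = delta$heart_rate_bpm)
  } else "unknown"
  est <- if (!is.null(thermal)) estimate_power(delta, thermal) else NULL
  structure(list(session_id = session_id, boundary = boundary,
                 delta_t = delta, bouts = bouts, regimen = regimen,
                 mobilization_minutes = mobilization_minutes(bouts),
                 est_power = est),
            class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf("<session_metrics> %s: %s, %d bout(s), %d active min, peak %.2f C\n",
              x$session_id, x$regimen, nrow(x$bouts),
              x$mobilization_minutes,
              if (nrow(x$bouts) > 0) max(x$bouts$peak_delta_t) else max(0, x$delta_t$delta_t)))
  invisible(x)
}

#' Discover session boundaries in a multi-day recording
#'
#' Simple documented heuristic for recordings without a session log: active
#' minutes (as in [detect_bouts()], computed on the absolute trace) are
#' clustered, and a new session starts whenever activity resumes after at
#' least `quiet_gap` minutes of quiet during which the device relaxed toward
#' ambient. The session start is placed one minute before the first active
#' sample (the zeroing row), and the zero reference is the reading there.
#'
#' @param series An absolute-scale [telemetry_series()].
#' @param quiet_gap Minimum quiet gap between sessions, minutes (default 60).
#' @param pad_end Minutes of trailing context appended after the last active
#'   minute (default 0).
#' @param min_len Minimum active minutes for a run to count as training
#'   (default 10 here -- the shortest prescribed bout -- so sensor noise over
#'   days of quiet cannot spawn sessions).
#' @param ... Passed to [detect_bouts()].
#' @return A list of session entries (`session_id`, `kind = NA`, `boundary`).
#' @export
discover_sessions <- function(series, quiet_gap = 60, pad_end = 0,
                              min_len = 10, ...) {
  s <- series$samples
  n <- nrow(s)
  if (n < 3) return(list())
  # median is a robust ambient reference over a mostly-quiet recording
  trace <- data.frame(timestamp = s$timestamp,
                      minute = as.numeric(difftime(s$timestamp, s$timestamp[1],
                                                   units = "mins")),
                      delta_t = s$temperature_c - stats::median(s$temperature_c),
                      heart_rate_bpm = s$heart_rate_bpm)
  bouts <- detect_bouts(trace, min_len = min_len, ...)
  mask <- attr(bouts, "active_mask")
  act <- which(mask)
  if (length(act) == 0) return(list())
  minute <- trace$minute
  breaks <- which(diff(minute[act]) >= quiet_gap)
  firsts <- act[c(1, breaks + 1)]
  lasts <- act[c(breaks, length(act))]
  lapply(seq_along(firsts), function(i) {
    i0 <- max(1, firsts[i] - 1L)
    i1 <- min(n, lasts[i] + pad_end)
    list(session_id = sprintf("S%02d", i), kind = NA_character_,
         boundary = session_boundary(s$timestamp[i0], s$timestamp[i1],
                                     zero_reference = s$temperature_c[i0]))
  })
}
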