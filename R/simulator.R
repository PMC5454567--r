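# Device and participant simulator: forward thermal model, heart-rate
# dynamics, a self-pacing HR controller, the five study protocols, and
# week-long multi-session recordings with ground truth for oracle testing.

#' Forward thermal model of the resistance unit
#'
#' Integrates `dT/dt = k * P(t) - lambda * (T - ambient_offset)` with
#' `T(0) = 0` at one-minute steps, holding power constant within each minute.
#' The exponential-step update is exact for piecewise-constant power, so for
#' constant `P` the output matches the closed form
#' `(k * P / lambda) * (1 - exp(-lambda * t))` to machine precision.
#' `cooling_rate = 0` degenerates to the pure work integrator
#' `T(n) = k * sum(P)`.
#'
#' @param power Non-negative per-minute power series, watts.
#' @param params A [thermal_params()] (or a list with the same fields;
#'   `cooling_rate = 0` is accepted here).
#' @return Numeric vector of session-relative temperatures, degrees C;
#'   element `i` is the temperature after minute `i`.
#' @export
simulate_thermal <- function(power, params) {
  k <- params$heat_coefficient
  lam <- params$cooling_rate
  amb <- params$ambient_offset %||% 0
  if (!is_scalar_num(k) || k <= 0) {
    ld_stop("`heat_coefficient` must be > 0")
  }
  if (!is_scalar_num(lam) || lam < 0) {
    ld_stop("`cooling_rate` must be >= 0")
  }
  if (length(power) == 0) ld_stop("`power` must be a nonempty series")
  if (any(!is.finite(power)) || any(power < 0)) {
    ld_stop("`power` values must be finite and >= 0")
  }
  if (lam == 0) {
    return(k * cumsum(power))
  }
  a <- exp(-lam)
  b <- (amb + k * power / lam) * (1 - a)
  as.numeric(stats::filter(b, a, method = "recursive"))
}

#' Simulate a heart-rate trace for a known power series
#'
#' First-order response toward `hr_rest + hr_gain * P(t)`:
#' `HR(t) = HR(t-1) + (hr_rest + g * P(t) - HR(t-1)) * (1 - exp(-1/tau))`
#' plus Gaussian noise, clipped to \[40, 220\] BPM. Deterministic given
#' `seed`.
#'
#' @param power Non-negative per-minute power series, watts.
#' @param params An [hr_params()].
#' @param seed Optional integer seed scoping the noise draws; when `NULL` the
#'   current RNG stream is consumed (used internally by the protocol
#'   simulator, which seeds the whole call).
#' @param hr0 Initial heart rate, BPM (defaults to `hr_rest`).
#' @return Numeric vector of BPM values, one per minute.
#' @export
simulate_hr <- function(power, params, seed = NULL, hr0 = params$hr_rest) {
  if (any(!is.finite(power)) || any(power < 0)) {
    ld_stop("`power` values must be finite and >= 0")
  }
  n <- length(power)
  noise <- hr_noise(n, params$hr_noise_sd, seed)
  alpha <- 1 - exp(-1 / params$tau)
  target <- params$hr_rest + params$hr_gain * power
  hr <- numeric(n)
  prev <- hr0
  for (i in seq_len(n)) {
    prev <- prev + (target[i] - prev) * alpha + noise[i]
    prev <- min(max(prev, 40), 220)
    hr[i] <- prev
  }
  hr
}

hr_noise <- function(n, sd, seed) {
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(numeric(n))
  if (is.null(seed)) stats::rnorm(n, 0, sd)
  else withr::with_seed(seed, stats::rnorm(n, 0, sd))
}

#' Self-pacing heart-rate controller
#'
#' Emulates a participant who watches their pulse oximeter and adjusts pedal
#' effort once per minute to hold a target heart-rate band, as in
#' self-controlled moderate-intensity training. The participant starts at the
#' feed-forward effort `(center - hr_rest) / hr_gain` and then trims power in
#' proportion to the observed HR error. With noise off, the simulated HR is
#' inside the band within a burn-in of at most 10 minutes.
#'
#' @param center,halfwidth Target band, BPM (e.g. 100 and 10 for the dosed
#'   protocol's 100 +/- 10 BPM).
#' @param duration Bout length, minutes.
#' @param participant A [participant_model()].
#' @param kp Controller gain, watts per BPM of error; default `0.4 / hr_gain`
#'   gives a well-damped loop for any gain.
#' @param seed Optional seed for the HR noise (see [simulate_hr()]).
#' @param noise Apply the participant's HR noise (`TRUE`) or run the loop
#'   noise-free (`FALSE`).
#' @return A list with per-minute `power` (watts) and the `hr` trace the
#'   controller reacted to (BPM).
#' @export
hr_controller <- function(center, halfwidth, duration, participant,
                          kp = NULL, seed = NULL, noise = TRUE) {
  hrp <- participant$hr
  if (center < hrp$hr_rest || center >= 220) {
    ld_stop(sprintf("unachievable band: center %g BPM outside [hr_rest=%g, 220)",
                    center, hrp$hr_rest), "legdose_config_error")
  }
  assert_num(halfwidth, "halfwidth", lower = 0)
  assert_num(duration, "duration", lower = 1)
  kp <- kp %||% (0.4 / hrp$hr_gain)
  n <- as.integer(duration)
  sd <- if (noise) hrp$hr_noise_sd else 0
  eps <- hr_noise(n, sd, seed)
  alpha <- 1 - exp(-1 / hrp$tau)
  p <- max(0, (center - hrp$hr_rest) / hrp$hr_gain)
  power <- numeric(n)
  hr <- numeric(n)
  prev <- hrp$hr_rest
  for (i in seq_len(n)) {
    power[i] <- p
    prev <- prev + (hrp$hr_rest + hrp$hr_gain * p - prev) * alpha + eps[i]
    prev <- min(max(prev, 40), 220)
    hr[i] <- prev
    p <- max(0, p + kp * (center - prev))
  }
  list(power = power, hr = hr)
}

PROTOCOL_KINDS <- c("mict", "dosed_mict", "hiit_wingate",
                    "desk_opportunistic", "bed_opportunistic")

# Ground-truth regimen label for each protocol kind.
KIND_REGIMEN <- c(mict = "MICT", dosed_mict = "MICT", hiit_wingate = "HIIT",
                  desk_opportunistic = "opportunistic",
                  bed_opportunistic = "opportunistic")

#' Protocol specification
#'
#' The five supported training protocols:
#' \describe{
#'   \item{`mict`}{moderate-intensity continuous training at a steady HR band
#'     (default 100 +/- 10 BPM) for 10-120 minutes.}
#'   \item{`dosed_mict`}{MICT at 100 +/- 10 BPM for exactly 30 minutes; this
#'     bout defines the personalized daily exercise dose.}
#'   \item{`hiit_wingate`}{modified Wingate interval protocol: 10 cycles of
#'     30 s high-intensity + 2 min moderate-intensity exercise (25 minutes
#'     total). Since sampling is fixed at 1 minute, each 30-s high block is
#'     represented as one 1-minute sample at the averaged power
#'     `(high + moderate) / 2`.}
#'   \item{`desk_opportunistic`, `bed_opportunistic`}{concurrent exercise at
#'     the office desk / in bed: alternating active blocks and breaks with
#'     geometric lengths and a per-block power level drawn uniformly from
#'     `power_range`.}
#' }
#'
#' @param kind One of `mict`, `dosed_mict`, `hiit_wingate`,
#'   `desk_opportunistic`, `bed_opportunistic`.
#' @param duration Minutes. Defaults: `mict` 30, `dosed_mict` fixed 30,
#'   `hiit_wingate` fixed 25, opportunistic kinds 120.
#' @param hr_center,hr_halfwidth Target HR band for the HR-controlled kinds.
#' @param high_power,moderate_power HIIT block powers, watts.
#' @param active_mean,break_mean Mean active-block and break lengths for the
#'   opportunistic kinds, minutes (geometric distributions on 1, 2, ...);
#'   `break_mean = 0` disables breaks. Defaults (12 and 8) give a ~60% duty
#'   cycle, i.e. about 70 active minutes in a 120-minute session.
#' @param power_range Per-block power range for opportunistic kinds, watts;
#'   defaults `c(30, 70)` at the desk and `c(20, 60)` in bed.
#' @param seed Optional RNG seed stored with the spec.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(kind, duration = NULL,
                          hr_center = 100, hr_halfwidth = 10,
                          high_power = 250, moderate_power = 80,
                          active_mean = 12, break_mean = 8,
                          power_range = NULL, seed = NULL) {
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% PROTOCOL_KINDS)) {
    ld_stop(sprintf("unknown protocol kind: %s (expected one of %s)",
                    paste(kind, collapse = "/"),
                    paste(PROTOCOL_KINDS, collapse = ", ")),
            "legdose_config_error")
  }
  if (kind == "dosed_mict") {
    if (!is.null(duration) && duration != 30) {
      ld_stop("dosed_mict duration is fixed at 30 minutes",
              "legdose_config_error")
    }
    duration <- 30
    if (hr_center != 100 || hr_halfwidth != 10) {
      ld_stop("dosed_mict band is fixed at 100 +/- 10 BPM",
              "legdose_config_error")
    }
  } else if (kind == "hiit_wingate") {
    if (!is.null(duration) && duration != 25) {
      ld_stop("hiit_wingate is 10 x (0.5 + 2) min = 25 minutes",
              "legdose_config_error")
    }
    duration <- 25
    assert_num(high_power, "high_power", lower = 0)
    assert_num(moderate_power, "moderate_power", lower = 0)
    if (high_power <= moderate_power) {
      ld_stop("hiit_wingate requires high_power > moderate_power",
              "legdose_config_error")
    }
  } else if (kind == "mict") {
    duration <- duration %||% 30
    if (duration < 10 || duration > 120) {
      ld_stop("mict duration must be within [10, 120] minutes",
              "legdose_config_error")
    }
  } else {
    duration <- duration %||% 120
    assert_num(duration, "duration", lower = 1)
    assert_num(active_mean, "active_mean", lower = 1)
    assert_num(break_mean, "break_mean", lower = 0)
    power_range <- power_range %||%
      if (kind == "desk_opportunistic") c(30, 70) else c(20, 60)
    if (length(power_range) != 2L || power_range[1] > power_range[2] ||
        power_range[1] < 0) {
      ld_stop("`power_range` must be c(min, max) with 0 <= min <= max",
              "legdose_config_error")
    }
  }
  structure(list(kind = kind, duration = as.integer(duration),
                 hr_center = hr_center, hr_halfwidth = hr_halfwidth,
                 high_power = high_power, moderate_power = moderate_power,
                 active_mean = active_mean, break_mean = break_mean,
                 power_range = power_range, seed = seed),
            class = "protocol_spec")
}

# Per-minute power (and HR, for controlled kinds) for one session. Consumes
# the current RNG stream; callers wrap in withr::with_seed().
build_session_signals <- function(spec, participant, noise) {
  n <- spec$duration
  sd <- if (noise) participant$hr$hr_noise_sd else 0
  hrp_eff <- participant$hr
  hrp_eff$hr_noise_sd <- sd
  part_eff <- participant
  part_eff$hr <- hrp_eff
  if (spec$kind %in% c("mict", "dosed_mict")) {
    ctl <- hr_controller(spec$hr_center, spec$hr_halfwidth, n, part_eff,
                         noise = noise)
    return(list(power = ctl$power, hr = ctl$hr))
  }
  if (spec$kind == "hiit_wingate") {
    # 30-second resolution: each 2.5-min cycle is 1 high + 4 moderate
    # half-minutes; average pairs down to the 1-minute sampling grid.
    half <- rep(c(spec$high_power, rep(spec$moderate_power, 4)), 10)
    power <- colMeans(matrix(half, nrow = 2))
  } else {
    power <- numeric(0)
    while (length(power) < n) {
      alen <- 1L + stats::rgeom(1, 1 / spec$active_mean)
      p <- stats::runif(1, spec$power_range[1], spec$power_range[2])
      power <- c(power, rep(p, alen))
      if (spec$break_mean > 0 && length(power) < n) {
        blen <- 1L + stats::rgeom(1, 1 / spec$break_mean)
        power <- c(power, rep(0, blen))
      }
    }
    power <- power[seq_len(n)]
  }
  list(power = power, hr = simulate_hr(power, hrp_eff))
}

# Placeholder SpO2/BP channels for a given power series.
build_vitals <- function(power, participant, noise) {
  n <- length(power)
  spo2_sd <- if (noise) 0.5 else 0
  bp_sd <- if (noise) 1 else 0
  spo2 <- clip(participant$spo2_baseline + stats::rnorm(n, 0, spo2_sd), 50, 100)
  active_min <- cumsum(power > 0)
  sys <- participant$bp_systolic +
    participant$bp_exercise_slope * active_min / 10 + stats::rnorm(n, 0, bp_sd)
  dia <- participant$bp_diastolic + stats::rnorm(n, 0, bp_sd)
  list(spo2 = spo2, systolic = sys, diastolic = dia)
}

#' Simulate one training session
#'
#' Generates minute telemetry for a protocol plus the ground-truth activity
#' trace used by the analysis oracles. The temperature channel is
#' session-relative (zeroed at start, so the first sample is exactly 0) with
#' additive Gaussian sensor noise; HR comes from the closed-loop controller
#' (HR-controlled kinds) or the first-order response (fixed-power kinds);
#' SpO2 stays at baseline with small noise and systolic blood pressure drifts
#' linearly with accumulated active minutes.
#'
#' @param spec A [protocol_spec()].
#' @param participant A [participant_model()].
#' @param start Session start timestamp.
#' @param seed Integer seed; every random draw in the call flows from it
#'   (defaults to the spec's `seed`, else 1).
#' @param noise Master noise switch: `FALSE` zeroes the temperature, HR, SpO2
#'   and BP noise for oracle tests.
#' @param temp_noise_sd Temperature sensor noise, degrees C (default 0.05).
#' @return A list of class `protocol_sim` with elements `series`
#'   (a zeroed [telemetry_series()] of `duration + 1` samples, including the
#'   minute-0 zero-reference sample), `boundary` (a [session_boundary()]),
#'   `activity` (data frame `timestamp`, `power_w`, `active` -- the ground
#'   truth), `kind` and `spec`.
#' @export
simulate_protocol <- function(spec, participant,
                              start = parse_ts("2015-06-01T09:00:00"),
                              seed = NULL, noise = TRUE,
                              temp_noise_sd = 0.05) {
  if (!inherits(spec, "protocol_spec")) {
    ld_stop("`spec` must be a protocol_spec", "legdose_config_error")
  }
  start <- as_ts(start, "start")
  seed <- seed %||% spec$seed %||% 1L
  withr::with_seed(seed, {
    sig <- build_session_signals(spec, participant, noise)
    n <- spec$duration
    t_true <- simulate_thermal(sig$power, participant$thermal)
    tsd <- if (noise) temp_noise_sd else 0
    temp <- c(0, t_true + stats::rnorm(n, 0, tsd))
    vit <- build_vitals(sig$power, participant, noise)
    ts <- minute_grid(start, n + 1L)
    samples <- data.frame(
      timestamp = ts,
      temperature_c = temp,
      heart_rate_bpm = c(participant$hr$hr_rest, sig$hr),
      spo2_pct = c(participant$spo2_baseline, vit$spo2),
      systolic_mmhg = c(participant$bp_systolic, vit$systolic),
      diastolic_mmhg = c(participant$bp_diastolic, vit$diastolic)
    )
    series <- telemetry_series(participant$participant_id, samples,
                               zeroed = TRUE)
    boundary <- session_boundary(ts[1], ts[n + 1L], zero_reference = temp[1])
    activity <- data.frame(timestamp = ts[-1], power_w = sig$power,
                           active = sig$power > 0)
    structure(list(series = series, boundary = boundary, activity = activity,
                   kind = spec$kind, regimen = unname(KIND_REGIMEN[spec$kind]),
                   spec = spec, seed = seed,
                   participant_id = participant$participant_id),
              class = "protocol_sim")
  })
}

#' Build a weekly schedule of dose-completing MICT bouts
#'
#' Convenience constructor for [simulate_week()] schedules: one MICT bout at
#' 100 +/- 10 BPM on each given day. The default 45-minute duration runs
#' well past the 30-minute dose definition, mirroring a participant who
#' keeps pedalling until (and after) the dose-completion alert arrives; the
#' margin makes the threshold crossing robust to session-to-session effort
#' variability and sensor noise.
#'
#' @param days Integer vector of dose days (1-7).
#' @param duration Bout length, minutes (default 45).
#' @param start_hour Clock hour of the bout (default 9).
#' @return A schedule list for [simulate_week()].
#' @export
dose_schedule <- function(days, duration = 45, start_hour = 9) {
  lapply(days, function(d) {
    list(day = d, spec = protocol_spec("mict", duration = duration),
         start_hour = start_hour)
  })
}

#' Simulate a continuous one-week recording
#'
#' Concatenates scheduled sessions into a single 7 x 1440 minute telemetry
#' series on the absolute temperature scale. The thermal state is continuous
#' across the week (the device relaxes toward ambient between sessions) and
#' every session is independently zeroed: its `session_boundary` records the
#' sensor reading at the session-start minute as `zero_reference`.
#'
#' @param schedule List of entries `list(day =, spec =, start_hour =)` with
#'   `day` in 1-7, `spec` a [protocol_spec()] and optional `start_hour`
#'   (sessions on the same day default to 9:00, 14:00, 19:00 in order).
#' @param participant A [participant_model()].
#' @param seed Integer seed; the whole week is bit-reproducible given it.
#' @param week_start Date of day 1.
#' @param ambient_c Absolute ambient temperature, degrees C.
#' @param noise Master noise switch as in [simulate_protocol()].
#' @param temp_noise_sd Temperature sensor noise, degrees C.
#' @return A list of class `legdose_week` with `series` (absolute-scale
#'   [telemetry_series()], `zeroed = FALSE`), `sessions` (list of
#'   `session_id`/`kind`/`boundary` entries), `activity` (week-long ground
#'   truth data frame) and `week_start`.
#' @export
simulate_week <- function(schedule, participant, seed = 1L,
                          week_start = as.Date("2015-06-01"),
                          ambient_c = 22, noise = TRUE,
                          temp_noise_sd = 0.05) {
  week_start <- as.Date(week_start)
  t0 <- as.POSIXct(format(week_start), tz = "UTC")
  n <- 7L * 1440L
  # resolve session start times and check the schedule
  day_count <- integer(7)
  default_hours <- c(9, 14, 19)
  sess <- lapply(schedule, function(e) {
    d <- e$day
    if (!is_scalar_num(d) || d < 1 || d > 7 || d != as.integer(d)) {
      ld_stop("schedule `day` must be an integer in 1..7",
              "legdose_scheduling_error")
    }
    if (!inherits(e$spec, "protocol_spec")) {
      ld_stop("schedule entries need a protocol_spec `spec`",
              "legdose_scheduling_error")
    }
    d <- as.integer(d)
    day_count[d] <<- day_count[d] + 1L
    if (day_count[d] > length(default_hours) && is.null(e$start_hour)) {
      ld_stop("at most 3 sessions per day without explicit start_hour",
              "legdose_scheduling_error")
    }
    hour <- e$start_hour %||% default_hours[day_count[d]]
    start <- t0 + ((d - 1L) * 24 + hour) * 3600
    list(spec = e$spec, start = start,
         end = start + e$spec$duration * 60)
  })
  if (length(sess) > 0) {
    ord <- order(vapply(sess, function(s) as.numeric(s$start), 0))
    sess <- sess[ord]
    starts <- vapply(sess, function(s) as.numeric(s$start), 0)
    ends <- vapply(sess, function(s) as.numeric(s$end), 0)
    if (any(starts[-1] < ends[-length(ends)])) {
      ld_stop("overlapping sessions in schedule", "legdose_scheduling_error")
    }
    if (ends[length(ends)] > as.numeric(t0) + n * 60) {
      ld_stop("schedule runs past the end of the week",
              "legdose_scheduling_error")
    }
  }
  withr::with_seed(seed, {
    hr_sd <- if (noise) participant$hr$hr_noise_sd else 0
    tsd <- if (noise) temp_noise_sd else 0
    spo2_sd <- if (noise) 0.5 else 0
    power <- numeric(n)
    hr <- participant$hr$hr_rest + stats::rnorm(n, 0, hr_sd)
    spo2 <- clip(participant$spo2_baseline + stats::rnorm(n, 0, spo2_sd), 50, 100)
    sys <- participant$bp_systolic + stats::rnorm(n, 0, if (noise) 1 else 0)
    dia <- participant$bp_diastolic + stats::rnorm(n, 0, if (noise) 1 else 0)
    boundaries <- vector("list", length(sess))
    for (i in seq_along(sess)) {
      s <- sess[[i]]
      sig <- build_session_signals(s$spec, participant, noise)
      vit <- build_vitals(sig$power, participant, noise)
      i0 <- as.integer((as.numeric(s$start) - as.numeric(t0)) / 60) + 1L
      idx <- i0 + seq_len(s$spec$duration)
      power[idx] <- sig$power
      hr[idx] <- sig$hr
      spo2[idx] <- vit$spo2
      sys[idx] <- vit$systolic
      dia[idx] <- vit$diastolic
      boundaries[[i]] <- list(session_id = sprintf("S%02d", i),
                              kind = s$spec$kind,
                              regimen = unname(KIND_REGIMEN[s$spec$kind]),
                              start_index = i0, spec = s$spec)
    }
    t_abs <- ambient_c +
      simulate_thermal(power, list(heat_coefficient = participant$thermal$heat_coefficient,
                                   cooling_rate = participant$thermal$cooling_rate,
                                   ambient_offset = 0))
    temp <- t_abs + stats::rnorm(n, 0, tsd)
    ts <- minute_grid(t0, n)
    hr <- clip(hr, 40, 220)
    samples <- data.frame(timestamp = ts, temperature_c = temp,
                          heart_rate_bpm = hr, spo2_pct = spo2,
                          systolic_mmhg = sys, diastolic_mmhg = dia)
    series <- telemetry_series(participant$participant_id, samples,
                               zeroed = FALSE)
    sessions <- lapply(boundaries, function(b) {
      i0 <- b$start_index
      list(session_id = b$session_id, kind = b$kind, regimen = b$regimen,
           boundary = session_boundary(ts[i0], ts[i0 + b$spec$duration],
                                       zero_reference = temp[i0]))
    })
    activity <- data.frame(timestamp = ts, power_w = power, active = power > 0)
    structure(list(series = series, sessions = sessions, activity = activity,
                   participant_id = participant$participant_id,
                   week_start = week_start, seed = seed),
              class = "legdose_week")
  })
}

#' @export
print.legdose_week <- function(x, ...) {
  cat(sprintf("<legdose_week> participant %s, week of %s: %d session(s)\n",
              x$participant_id, format(x$week_start), length(x$sessions)))
  invisible(x)
}
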