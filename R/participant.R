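# Participant and device parameter containers, plus cohort generation.

#' Thermal parameters of the resistance unit
#'
#' First-order (Newton cooling) model of the device's resistance unit:
#' `dT/dt = k * P(t) - lambda * (T - ambient_offset)` with `T(0) = 0` on the
#' session-relative scale. The steady-state rise for constant power `P` is
#' `k * P / lambda`.
#'
#' @param heat_coefficient `k`, degrees C per watt-minute: temperature gain
#'   per unit mechanical work. Default 0.005, chosen so a default participant
#'   pedalling at ~100 W for 30 min produces a delta-t near the middle of the
#'   observed 4.5-10.5 degrees C dose range.
#' @param cooling_rate `lambda`, per minute: Newtonian relaxation toward
#'   ambient. Default 0.05 (time constant 20 min).
#' @param ambient_offset Ambient temperature relative to the session zero,
#'   degrees C (default 0).
#' @return An object of class `thermal_params`.
#' @export
thermal_params <- function(heat_coefficient = 0.005, cooling_rate = 0.05,
                           ambient_offset = 0) {
  assert_num(heat_coefficient, "heat_coefficient", lower = 1e-12)
  assert_num(cooling_rate, "cooling_rate", lower = 1e-12)
  assert_num(ambient_offset, "ambient_offset")
  structure(list(heat_coefficient = heat_coefficient,
                 cooling_rate = cooling_rate,
                 ambient_offset = ambient_offset),
            class = "thermal_params")
}

#' Heart-rate response parameters
#'
#' First-order heart-rate model: HR relaxes toward `hr_rest + hr_gain * P`
#' with time constant `tau` minutes, plus Gaussian beat-to-beat noise.
#'
#' @param hr_rest Resting heart rate, BPM (must lie in \[40, 100\]).
#' @param hr_gain `g`, BPM per watt of leg work.
#' @param tau Time constant of the HR response, minutes.
#' @param hr_noise_sd Standard deviation of minute-to-minute HR noise, BPM.
#' @return An object of class `hr_params`.
#' @export
hr_params <- function(hr_rest = 65, hr_gain = 0.35, tau = 1, hr_noise_sd = 2) {
  assert_num(hr_rest, "hr_rest", lower = 40, upper = 100)
  assert_num(hr_gain, "hr_gain", lower = 1e-12)
  assert_num(tau, "tau", lower = 1e-12)
  assert_num(hr_noise_sd, "hr_noise_sd", lower = 0)
  structure(list(hr_rest = hr_rest, hr_gain = hr_gain, tau = tau,
                 hr_noise_sd = hr_noise_sd),
            class = "hr_params")
}

#' Participant model
#'
#' All physiological and device parameters the simulator needs for one
#' participant. Blood pressure and SpO2 are carried as data channels with
#' simple placeholder dynamics only (constant baselines, linear systolic
#' drift during active MICT minutes).
#'
#' @param participant_id Opaque identifier.
#' @param thermal A [thermal_params()].
#' @param hr An [hr_params()].
#' @param spo2_baseline Resting blood oxygen saturation, percent.
#' @param bp_systolic,bp_diastolic Resting blood pressure, mmHg.
#' @param bp_exercise_slope Systolic rise in mmHg per 10 minutes of active
#'   moderate exercise.
#' @return An object of class `participant_model`.
#' @export
participant_model <- function(participant_id = "P01",
                              thermal = thermal_params(),
                              hr = hr_params(),
                              spo2_baseline = 98,
                              bp_systolic = 120,
                              bp_diastolic = 80,
                              bp_exercise_slope = 3) {
  if (!inherits(thermal, "thermal_params")) thermal <- do.call(thermal_params, thermal)
  if (!inherits(hr, "hr_params")) hr <- do.call(hr_params, hr)
  assert_num(spo2_baseline, "spo2_baseline", lower = 50, upper = 100)
  assert_num(bp_systolic, "bp_systolic", lower = 60, upper = 250)
  assert_num(bp_diastolic, "bp_diastolic", lower = 30, upper = 150)
  assert_num(bp_exercise_slope, "bp_exercise_slope", lower = 0)
  structure(list(participant_id = as.character(participant_id)[1],
                 thermal = thermal, hr = hr,
                 spo2_baseline = spo2_baseline,
                 bp_systolic = bp_systolic, bp_diastolic = bp_diastolic,
                 bp_exercise_slope = bp_exercise_slope),
            class = "participant_model")
}

#' @export
print.participant_model <- function(x, ...) {
  cat(sprintf(
    "<participant_model> %s: k=%.4g C/(W*min), lambda=%.3g /min, hr_rest=%g, hr_gain=%.3g BPM/W\n",
    x$participant_id, x$thermal$heat_coefficient, x$thermal$cooling_rate,
    x$hr$hr_rest, x$hr$hr_gain))
  invisible(x)
}

#' Default cohort heterogeneity ranges
#'
#' Uniform ranges for the per-participant parameters drawn by
#' [simulate_cohort()]. Defaults are chosen so that 30-minute dosed-MICT
#' doses of a simulated cohort span roughly the observed 4.5-10.5 degrees C
#' range with a mean near 7.8 degrees C.
#'
#' @return A named list of `c(min, max)` ranges.
#' @export
cohort_ranges <- function() {
  list(heat_coefficient = c(0.004, 0.006),
       cooling_rate = c(0.045, 0.055),
       hr_rest = c(60, 70),
       hr_gain = c(0.32, 0.40),
       tau = c(0.8, 1.3))
}

#' Draw a heterogeneous cohort of participants
#'
#' Reproducible uniform draws of participant parameters. Point ranges
#' (`min == max`) pin a parameter.
#'
#' @param n Number of participants (>= 1).
#' @param heterogeneity Named list of `c(min, max)` ranges, see
#'   [cohort_ranges()]. Missing entries fall back to the defaults.
#' @param seed Integer RNG seed; the same seed reproduces the cohort exactly.
#' @return A list of `n` [participant_model()] objects with ids `P01`, `P02`,
#'   ...
#' @export
simulate_cohort <- function(n, heterogeneity = cohort_ranges(), seed = 1L) {
  assert_num(n, "n", lower = 1)
  ranges <- utils::modifyList(cohort_ranges(), heterogeneity)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      ld_stop(sprintf("degenerate range for `%s`: min must be <= max", nm))
    }
  }
  withr::with_seed(seed, {
    draw <- function(nm) stats::runif(n, ranges[[nm]][1], ranges[[nm]][2])
    k <- draw("heat_coefficient")
    lam <- draw("cooling_rate")
    rest <- draw("hr_rest")
    gain <- draw("hr_gain")
    tau <- draw("tau")
    lapply(seq_len(n), function(i) {
      participant_model(
        participant_id = sprintf("P%02d", i),
        thermal = thermal_params(k[i], lam[i]),
        hr = hr_params(hr_rest = rest[i], hr_gain = gain[i], tau = tau[i])
      )
    })
  })
}

#' Closed-form dosed-MICT dose prediction
#'
#' For steady exercise at the heart-rate band centre `hr_center`, the mean
#' power demand is `(hr_center - hr_rest) / hr_gain` and the temperature rise
#' after `duration` minutes follows the constant-power solution
#' `(k * P / lambda) * (1 - exp(-lambda * duration))`. Useful as an
#' independent oracle for calibration tests.
#'
#' @param participant A [participant_model()].
#' @param duration Bout duration in minutes (default 30).
#' @param hr_center Target heart-rate band centre, BPM (default 100).
#' @return Predicted delta-t at `duration` minutes, degrees C.
#' @export
predicted_dose <- function(participant, duration = 30, hr_center = 100) {
  th <- participant$thermal
  p_bar <- max(0, (hr_center - participant$hr$hr_rest) / participant$hr$hr_gain)
  (th$heat_coefficient * p_bar / th$cooling_rate) *
    (1 - exp(-th$cooling_rate * duration))
}
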