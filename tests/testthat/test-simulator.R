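# device_simulator: thermal model, HR dynamics, controller, protocols,
# weeks, cohorts.

test_that("thermal model: zero input, closed form, heat bookkeeping, monotonicity", {
  th <- thermal_params(0.01, 0.05)
  expect_equal(simulate_thermal(rep(0, 20), th), rep(0, 20))

  # constant power matches (kP/lambda)(1 - exp(-lambda t)); frozen oracle
  # value 20 * (1 - e^-1.5) = 15.5373961
  out <- simulate_thermal(rep(100, 30), th)
  expect_lt(abs(out[30] - 15.5373961) / 15.5373961, 0.01)

  # across a parameter grid, 1-min stepping stays within 1% of closed form
  for (k in c(0.003, 0.005, 0.008)) {
    for (lam in c(0.02, 0.05, 0.1, 0.2)) {
      for (p in c(50, 120)) {
        sim <- simulate_thermal(rep(p, 40), thermal_params(k, lam))
        cf <- (k * p / lam) * (1 - exp(-lam * (1:40)))
        expect_lt(max(abs(sim - cf) / cf), 0.01)
      }
    }
  }

  # lambda = 0 is the exact work integrator
  pw <- c(10, 0, 50, 120, 30)
  expect_equal(simulate_thermal(pw, list(heat_coefficient = 0.01,
                                         cooling_rate = 0)),
               0.01 * cumsum(pw))

  # dominance: P1 >= P2 pointwise implies T1 >= T2 pointwise
  withr::with_seed(42, {
    for (i in 1:20) {
      p2 <- runif(60, 0, 150)
      p1 <- p2 + runif(60, 0, 50)
      expect_true(all(simulate_thermal(p1, th) >=
                        simulate_thermal(p2, th) - 1e-12))
    }
  })

  expect_error(simulate_thermal(rep(10, 5), thermal_params(0.01, 0.05)[
    c("cooling_rate", "ambient_offset")]), class = "legdose_validation_error")
  expect_error(simulate_thermal(numeric(0), th),
               class = "legdose_validation_error")
  expect_error(simulate_thermal(c(-1, 5), th),
               class = "legdose_validation_error")
})

test_that("heart rate: fixed point, first-order step response, determinism", {
  hp <- hr_params(hr_rest = 65, hr_gain = 0.35, tau = 2, hr_noise_sd = 0)
  expect_equal(simulate_hr(rep(0, 15), hp), rep(65, 15))

  # step to constant P: monotone approach, within 1% of hr_rest + g*P by 5 tau
  hr <- simulate_hr(rep(100, 30), hp)
  target <- 65 + 0.35 * 100
  expect_true(all(diff(hr) > -1e-12))
  expect_lt(abs(hr[10] - target), 0.01 * (target - 65))

  hpn <- hr_params(hr_noise_sd = 3)
  expect_identical(simulate_hr(rep(80, 40), hpn, seed = 7),
                   simulate_hr(rep(80, 40), hpn, seed = 7))
  expect_false(identical(simulate_hr(rep(80, 40), hpn, seed = 7),
                         simulate_hr(rep(80, 40), hpn, seed = 8)))
})

test_that("hr controller holds the band, scales power with demand, and validates", {
  p <- default_pt()
  ctl <- hr_controller(100, 10, 40, p, noise = FALSE)
  expect_true(all(ctl$hr[10:40] >= 90 & ctl$hr[10:40] <= 110))

  hi <- hr_controller(120, 10, 40, p, noise = FALSE)
  expect_gt(mean(hi$power), mean(ctl$power))

  rest <- hr_controller(p$hr$hr_rest, 10, 30, p, noise = FALSE)
  expect_lt(mean(tail(rest$power, 10)), 1)

  expect_error(hr_controller(50, 10, 30, p), class = "legdose_config_error")
  expect_error(hr_controller(240, 10, 30, p), class = "legdose_config_error")
})

test_that("protocol specs enforce the protocol invariants", {
  expect_equal(protocol_spec("dosed_mict")$duration, 30L)
  expect_equal(protocol_spec("hiit_wingate")$duration, 25L)
  expect_error(protocol_spec("dosed_mict", duration = 40),
               class = "legdose_config_error")
  expect_error(protocol_spec("mict", duration = 5),
               class = "legdose_config_error")
  expect_error(protocol_spec("mict", duration = 150),
               class = "legdose_config_error")
  expect_error(protocol_spec("zumba"), class = "legdose_config_error")
})

test_that("hiit_wingate has exactly 10 high-power minutes in 25", {
  sim <- sim_session("hiit_wingate", seed = 3)
  expect_equal(nrow(sim$activity), 25L)
  expect_equal(nrow(sim$series$samples), 26L)  # + minute-0 zero row
  spec <- protocol_spec("hiit_wingate")
  high <- (spec$high_power + spec$moderate_power) / 2
  expect_equal(sum(sim$activity$power_w == high), 10L)
  expect_equal(sum(sim$activity$power_w == spec$moderate_power), 15L)
})

test_that("dosed MICT reproduces the closed-form dose calibration", {
  # k chosen so (k * Pbar / lambda)(1 - e^{-30 lambda}) = 10.5 (the full dose)
  p <- default_pt(thermal = thermal_params(k_for_dose(10.5), 0.05))
  sim <- simulate_protocol(protocol_spec("dosed_mict"), p, seed = 2,
                           noise = FALSE)
  dt30 <- tail(sim$series$samples$temperature_c, 1)
  expect_lt(abs(dt30 - 10.5) / 10.5, 0.02)
})

test_that("opportunistic sessions follow the break model", {
  nobreak <- sim_session("bed_opportunistic", seed = 2, break_mean = 0)
  expect_equal(sum(nobreak$activity$active), 120L)

  withbreak <- sim_session("desk_opportunistic", seed = 2)
  expect_lt(sum(withbreak$activity$active), 120L)
  expect_gt(sum(withbreak$activity$active), 0L)
})

test_that("sessions are zeroed, deterministic given the seed, and valid", {
  a <- sim_session("dosed_mict", seed = 9)
  b <- sim_session("dosed_mict", seed = 9)
  expect_identical(a$series$samples, b$series$samples)
  expect_identical(a$activity, b$activity)
  expect_equal(a$series$samples$temperature_c[1], 0)
  expect_equal(a$boundary$zero_reference, 0)
  expect_false(identical(a$series$samples,
                         sim_session("dosed_mict", seed = 10)$series$samples))
})

test_that("simulate_week: scheduled doses, empty schedule, truncation, overlap", {
  p <- default_pt()
  week <- simulate_week(dose_schedule(c(1, 3, 4, 5, 7), duration = 45), p,
                        seed = 21, noise = FALSE)
  expect_length(week$sessions, 5L)
  expect_equal(nrow(week$series$samples), 7L * 1440L)
  # each dose session's delta-t at minute 30 equals the isolated calibration
  # bout (simulator oracle: noise-free sessions are identical), so every
  # session reaches the participant's dose
  iso <- simulate_protocol(protocol_spec("dosed_mict"), p, noise = FALSE)
  dose <- tail(iso$series$samples$temperature_c, 1)
  d30 <- vapply(week$sessions, function(s) {
    tr <- compute_delta_t(week$series, s$boundary)
    tr$delta_t[tr$minute == 30]
  }, 0)
  expect_true(all(abs(d30 - dose) / dose < 0.005))
  expect_true(all(vapply(week$sessions, function(s) {
    max(compute_delta_t(week$series, s$boundary)$delta_t)
  }, 0) >= dose * 0.999))
  # and the closed-form constant-power solution is within a few percent of
  # the controller-driven bout (burn-in boost stays small)
  expect_lt(abs(dose - predicted_dose(p)) / predicted_dose(p), 0.03)

  empty <- simulate_week(list(), p, seed = 1)
  expect_length(empty$sessions, 0L)
  expect_equal(nrow(empty$series$samples), 7L * 1440L)
  expect_lt(max(abs(empty$series$samples$temperature_c - 22)), 1)

  # a 15-minute truncated bout peaks below the 30-minute dose
  tr <- simulate_week(list(list(day = 2, spec = protocol_spec("mict", duration = 15))),
                      p, seed = 4, noise = FALSE)
  peak <- max(compute_delta_t(tr$series, tr$sessions[[1]]$boundary)$delta_t)
  expect_lt(peak, dose)

  expect_error(
    simulate_week(list(list(day = 1, spec = protocol_spec("mict", duration = 60),
                            start_hour = 9),
                       list(day = 1, spec = protocol_spec("mict", duration = 60),
                            start_hour = 9.5)), p),
    class = "legdose_scheduling_error")

  expect_identical(simulate_week(dose_schedule(c(2, 6)), p, seed = 3)$series$samples,
                   simulate_week(dose_schedule(c(2, 6)), p, seed = 3)$series$samples)
})

test_that("cohorts: point ranges, determinism, dose span, degenerate ranges", {
  point <- lapply(cohort_ranges(), function(r) rep(mean(r), 2))
  c1 <- simulate_cohort(1, point, seed = 4)
  expect_equal(c1[[1]]$thermal$heat_coefficient, mean(cohort_ranges()$heat_coefficient))

  expect_identical(simulate_cohort(5, seed = 6), simulate_cohort(5, seed = 6))

  # k range spanning doses 4.5-10.5 C keeps every simulated dose in range
  rng <- list(heat_coefficient = c(k_for_dose(4.5), k_for_dose(10.5)),
              cooling_rate = c(0.05, 0.05), hr_rest = c(65, 65),
              hr_gain = c(0.35, 0.35), tau = c(1, 1))
  co <- simulate_cohort(7, rng, seed = 3)
  doses <- vapply(co, function(pp) {
    sim <- simulate_protocol(protocol_spec("dosed_mict"), pp, seed = 5)
    tail(sim$series$samples$temperature_c, 1)
  }, 0)
  expect_true(all(doses > 4.5 * 0.93 & doses < 10.5 * 1.07))

  expect_error(simulate_cohort(3, list(heat_coefficient = c(0.01, 0.002))),
               class = "legdose_validation_error")
})
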