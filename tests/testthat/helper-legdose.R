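# Shared fixtures: everything is generated in code at test time.

default_pt <- function(...) participant_model(...)

# heat coefficient that yields a given 30-min dosed-MICT dose for the default
# participant (mean power 100 W, lambda 0.05) -- the closed-form calibration
k_for_dose <- function(dose, lambda = 0.05, p_bar = 100, duration = 30) {
  dose * lambda / (p_bar * (1 - exp(-lambda * duration)))
}

sim_session <- function(kind, seed = 1, participant = default_pt(),
                        noise = TRUE, ...) {
  simulate_protocol(protocol_spec(kind, ...), participant,
                    seed = seed, noise = noise)
}

session_label <- function(kind, seed, participant = default_pt(),
                          noise = TRUE) {
  sim <- sim_session(kind, seed, participant, noise)
  analyze_session(sim$series, sim$boundary)$regimen
}

# Jaccard overlap and recall between the detected active mask and the
# simulator's ground-truth activity (the minute-0 zeroing sample is dropped).
mask_scores <- function(sim) {
  mx <- analyze_session(sim$series, sim$boundary)
  mask <- attr(mx$bouts, "active_mask")[-1]
  truth <- sim$activity$active
  c(jaccard = sum(mask & truth) / max(1, sum(mask | truth)),
    recall = sum(mask & truth) / max(1, sum(truth)))
}

# a calibrated prescription for the default participant
calibrated_rx <- function(participant = default_pt(), seed = 11) {
  cal <- simulate_protocol(protocol_spec("dosed_mict"), participant, seed = seed)
  mx <- analyze_session(cal$series, cal$boundary, session_id = "CAL")
  calibrate_dose(mx, participant_id = participant$participant_id)
}

# write a small telemetry CSV from text lines
write_csv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
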