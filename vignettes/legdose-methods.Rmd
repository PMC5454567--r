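---
title: "Temperature-based exercise dosing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-based exercise dosing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(legdose)
```

## The measurement idea

A portable resistance leg trainer is instrumented with a wireless
temperature sensor on its resistance unit. Pedalling converts mechanical
work into heat, so the rise of the unit's temperature above its session
start value — written Δt°, in °C — tracks the user's leg work output.
Before every training session the reading is zeroed; the sensor then reports
once per minute. Because Δt° grows with both intensity and duration, the Δt°
reached in a standard bout (30 minutes of moderate-intensity continuous
training, MICT, at a heart rate of 100 ± 10 BPM) can serve as a
*single-number daily exercise dose*, analogous to a drug dose: a user "takes
the dose" on any day on which their Δt° reaches that personal threshold, a
cloud service mails an automatic notification at the crossing, and weekly
adherence is simply the count of notified days (5 or more = compliant).

`legdose` implements that pipeline end to end — simulator, session
analysis, dose engine, and a file-based CLI — so the method can be studied,
tested and extended without access to the original hardware. No public
dataset accompanies the original system, so the simulator is a first-class,
tested component: every analysis stage is validated against simulated ground
truth.

## The device and participant models

**Thermal model.** The resistance unit is modelled as a first-order
(Newton cooling) system,

$$\frac{dT}{dt} = k\,P(t) - \lambda\,(T - T_{amb}),\qquad T(0)=0,$$

with heat coefficient $k$ (°C per watt-minute), cooling rate $\lambda$ (per
minute) and ambient offset $T_{amb}$. For constant power the solution is
$(kP/\lambda)(1-e^{-\lambda t})$ with steady state $kP/\lambda$. This is the
simplest model that reproduces the two qualitative features reported for the
real device: a concave rise during steady exercise, and a slope that scales
with intensity. `simulate_thermal()` integrates it with an exact
exponential step per minute (power held constant within each minute), so the
constant-power closed form is matched to machine precision and $\lambda = 0$
degenerates to an exact work integrator — both are tested invariants.

**Heart rate.** HR relaxes toward $HR_{rest} + g\,P$ with a first-order
time constant $\tau$ (≈ 1 minute) plus Gaussian minute-to-minute noise
(default SD 2 BPM), clipped to [40, 220] BPM.

**Self-pacing controller.** Participants in the deployed system watched a
pulse oximeter and adjusted their own effort. `hr_controller()` emulates
this: the rider starts at the feed-forward effort $(HR_{target} -
HR_{rest})/g$ and trims power in proportion to the observed HR error (gain
$0.4/g$ W per BPM, a well-damped loop). With noise off, HR settles inside
the target band within 10 minutes; asking for the resting HR yields zero
power.

**Defaults and why.** The defaults define the simulated world once:

| parameter | default | rationale |
|---|---|---|
| $k$ | 0.005 °C/(W·min) | with the default rider (~100 W at 100 BPM) the 30-min dose is ≈ 7.8 °C, the centre of the reported 4.5–10.5 °C dose range |
| $\lambda$ | 0.05 /min | 20-minute device time constant; gives the reported concave session shapes |
| $HR_{rest}$, $g$, $\tau$ | 65 BPM, 0.35 BPM/W, 1 min | textbook values for healthy adults on light leg exercise |
| temperature noise | SD 0.05 °C | typical wireless thermistor noise; no sensor noise figure is reported for the original hardware |
| SpO2 | 98 % ± 0.5 | observed to hold a steady state in field recordings |
| systolic BP | +3 mmHg per 10 active min | placeholder for the expected MICT systolic drift |

Cohort heterogeneity (`simulate_cohort()`) draws $k \in [0.004, 0.006]$,
$\lambda \in [0.045, 0.055]$, $HR_{rest} \in [60, 70]$, $g \in [0.32,
0.40]$, $\tau \in [0.8, 1.3]$ uniformly, which spans 30-minute doses of
roughly 4.5–10.5 °C with mean ≈ 7.6 — deliberately matched to the reported
inter-participant spread, which is treated as a plausibility range, not a
reproduction target (it came from 7 real volunteers).

## The five protocols

1. **MICT** — HR-controlled steady exercise, 10–120 minutes.
2. **Dosed MICT** — MICT at 100 ± 10 BPM for exactly 30 minutes; defines
   the dose.
3. **Modified Wingate HIIT** — 10 cycles of 30 s high + 2 min moderate
   intensity (25 minutes). Sampling is fixed at 1 minute, so each 30-s high
   block is represented as one 1-minute sample at the averaged power
   $(P_{high}+P_{mod})/2$; the simulator builds the trace at 30-s resolution
   and averages pairs, which yields exactly 10 elevated minutes.
4. **Desk** and 5. **in-bed opportunistic training** — alternating active
   blocks and breaks with geometric lengths (means 12 and 8 minutes) and a
   per-block power drawn uniformly (30–70 W desk, 20–60 W bed). The ~60%
   duty cycle makes a 2-hour session average ≈ 70 active minutes, matching
   the reported "prolonged leg mobilization" scale.

`simulate_week()` concatenates scheduled sessions into one continuous
7 × 1440-minute absolute-temperature recording; the thermal state relaxes to
ambient between sessions and each session is independently zeroed (its
boundary records the sensor reading at the start minute). Every
`simulate_*` call is bit-reproducible from its seed.

**"Completed" dose bouts.** The dose threshold is *defined* as Δt° at
minute 30 of a calibration bout, so a bout stopped at exactly 30.0 minutes
ends *at* the threshold and sensor noise makes the crossing a coin flip. In
the deployed workflow users pedal until the alert arrives, so the weekly
schedule helper `dose_schedule()` uses 45-minute MICT bouts: the ≈ 15%
Δt° margin makes completion robust to session-to-session effort variability
(measured SD ≈ 0.15 °C) while staying well inside the 10–120-minute MICT
envelope. The fixed 30-minute `dosed_mict` protocol is unchanged.

## Session analysis

`compute_delta_t()` subtracts the session zero reference; the first value is
exactly 0 and missing minutes are never interpolated.

**Bout segmentation** (`detect_bouts()`). A minute is active when (a) the
centered finite-difference slope is ≥ 0.05 °C/min, or (b) the 3-point
smoothed trace is still rising, or (c) the *heat-input rate*
$q(t) = \Delta t'(t) + \lambda\,\Delta t(t)$ — which equals $kP(t)$ under
the model, i.e. the deviation from free Newtonian cooling — pooled over 3
minutes is ≥ 0.05 °C/min. Clause (c) exists because a slope-only rule is
physically blind near the thermal steady state, where continued pedalling
holds the temperature flat; on long opportunistic sessions this blind spot
alone breaks the ≥ 0.9 Jaccard recovery requirement. The binary mask is
despeckled with a 3-point majority vote, run edges are refined with the
sharper 1-minute heat rate, 1–3-minute in-run windows with negligible heat
input are punched back out (short breaks that pooling bridged), and each
candidate run must clear a robust noise floor (2.3 σ, estimated from the
quiet minutes via MAD) in total heat input. Runs closer than 5 minutes are
merged and merged runs with fewer than 3 active minutes are discarded. None
of these thresholds is prescribed by the original method, which marks active
training only visually, so they are package design decisions, fixed here and
validated against simulated ground truth: across seeded opportunistic
sessions the mask recovers ground-truth active minutes with mean Jaccard
≥ 0.9 (individual sessions vary with their random break structure).

**Regimen classification** (`classify_regimen()`) is deterministic and
rule-based, in order:

* **HIIT** — ≥ 6 alternations between high- and moderate-slope states inside
  the dominant bout. Alternations are counted as peaks of the
  median-detrended 1-minute slope exceeding 0.15 °C/min with median spacing
  ≤ 4 minutes (the Wingate-style cycle is 2.5 min). The amplitude floor
  keeps sensor noise from alternating, and the spacing cap keeps
  block-structured opportunistic sessions (10–20-minute alternations) out.
* **MICT** — one dominant bout (≥ 80% of active minutes), duration 10–120
  min, at most one in-bout cooling minute, and a high goodness of fit
  (R² ≥ 0.75) of `slope ~ delta_t` inside the bout. The regression is the
  cooling-corrected version of "low slope variability": constant power
  implies $\Delta t' = kP - \lambda \Delta t$, a straight line in that
  plane. A raw slope CV fails here by construction — even a noise-free
  120-minute constant-power bout has slope CV ≈ 1.4, purely from Newton
  cooling.
* **opportunistic** — multiple bouts, in-bout cooling, or a poor MICT fit.
* **unknown** — e.g. a single clean bout shorter than 10 minutes.

On simulated protocols the labels are recovered 100% noise-free and ≥ 90%
at default noise (both tested over seeded sessions).

**Work-output inversion** (`estimate_power()`):
$\hat P(t) = (\Delta t'(t) + \lambda(\Delta t - T_{amb}))/k$ with centered
differences (one-sided at edges), floored at 0 W. On noise-free
piecewise-constant power it recovers the truth within 2% away from the
edges and change-point minutes; estimates in the first two minutes and
within a minute of a power step carry the usual finite-difference transient.

## Dose engine

* `calibrate_dose()` — dose = Δt° at minute 30 of a MICT-classified
  calibration session of at least 30 minutes whose HR stayed mostly (≥ 80%
  of post-burn-in minutes) inside 100 ± 10 BPM.
* `dose_progress()` — percent of dose (5.25 °C of 10.5 °C reads 50),
  capped at 100 once exceeded.
* `detect_dose_events()` — first threshold crossing (inclusive ≥) per
  calendar day, at minute resolution; later crossings the same day are
  debounced. Days are bounded at local midnight of the telemetry clock (the
  source never defines the day window); a session spanning midnight credits
  the day of the crossing, matching the event-time semantics of an e-mail
  alert. Events are an in-memory/CSV log standing in for the real e-mail
  transport.
* `weekly_adherence()` / `cohort_report()` — tick/cross day flags,
  `compliant = dose_days >= 5`, and the supervisor's cohort table (ASCII
  `x`/`.` to stay terminal-safe).
* `detect_incomplete_bouts()` — MICT-classified sessions peaking below the
  threshold; opportunistic sessions below threshold are deliberately not
  flagged.
* Both prescription modes are supported: each participant's own dose
  (`personal`) or one cohort-mean dose for everyone (`cohort-mean`, as used
  in the original home-training week); `apply_dose_mode()` converts.

## What a green test does and does not establish

The generator reproduces the *structure* the analysis assumes: first-order
thermal and HR dynamics, self-paced control, block-wise opportunistic
activity, independent Gaussian sensor noise. Real recordings additionally
contain ambient drift, wireless dropouts longer than single minutes,
quantized sensor output, day-to-day physiological drift and behaviourally
correlated effort — none of which is modelled (dropouts are supported by the
data model but not generated by default). Green tests therefore establish
internal consistency of method and implementation under the stated world,
not clinical validity; the originally reported field numbers (dose 7.8 ± 1.6 °C,
4.4 ± 1.8 notified days, 73.7 ± 29.7 mobilization minutes) are used only to
choose plausible defaults.

## Numerical choices and degenerate inputs

* Exponential-step thermal integration: exact for piecewise-constant power;
  `cooling_rate = 0` is accepted by `simulate_thermal()` as the pure
  integrator (the participant-level constructor still requires λ > 0).
* Threshold comparisons are inclusive (`>=`); ties at the dose threshold
  count as crossings.
* Timestamps are ISO-8601 local time without timezone, carried internally
  as UTC so arithmetic is DST-free; the CSV writer emits the shortest
  decimal representation that round-trips exactly, so write→read→write is
  byte-identical.
* Empty schedules, empty bout lists, header-only telemetry files and
  zero-event weeks all flow through with empty-but-typed results.
* A d-minute session carries d+1 telemetry rows: the minute-0 zeroing row is
  included so `zero_reference` equals the first in-session sample and
  `delta_t[0] = 0` exactly.

## Known limitations

* Power units are nominal watts; only ratios are identifiable from Δt°, so
  `estimate_power()` needs externally supplied device parameters.
* BP/SpO2 are placeholder channels, not physiology.
* The HIIT rule needs the alternation to survive 1-minute sampling; real
  protocols with sub-30-s bursts would need faster sampling.
* `discover_sessions()` is a deliberately simple heuristic (activity
  clusters separated by ≥ 60 quiet minutes, ≥ 10 active minutes); a session
  log is always preferred when available.
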