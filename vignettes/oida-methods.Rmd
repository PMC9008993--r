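---
title: "Detecting optimal stimulation intervals for FES-cycling from crank torque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting optimal stimulation intervals for FES-cycling from crank torque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(oida)
```

## The problem

In functional electrical stimulation (FES) cycling, paralyzed leg muscles
are activated through surface electrodes to drive the crank of a trike.
Each muscle channel must be switched on only over the part of the cycle
where that muscle actually propels the crank; elsewhere it resists the
motion and wastes contractile effort. Stimulation patterns are commonly
tuned by hand, which is slow and fatiguing for the rider.

This package determines the pattern from measurements instead. During a
fitting session an examiner turns the rider's legs slowly (a target of
5 RPM with a generous ±50 % gate) while an instrumented crank records
per-side torque. A set of *passive* cycles (no stimulation) is recorded
first, then stimulation is switched on continuously and a set of *active*
cycles follows. The **net torque** — mean active minus mean passive torque
at the same cycle position — is positive exactly where the stimulated
muscle contributes, and the detected stimulation interval is the positive
run of the net torque containing its maximum:

1. align the sensor streams (the power meter reports ~200 ms late, the
   IMUs ~40 ms late) onto a common 100 Hz clock;
2. segment pedalling cycles from the chosen control signal and reject
   cycles outside the cadence gate, plus the first accepted active cycle
   (stimulation-onset transient);
3. resample each remaining cycle onto a fixed position template — crank
   angle 0–360° in 1° steps or cycling phase 0–100 % in 1 % steps — **as a
   function of position, not time**;
4. average, subtract, and locate the positive run around the net-torque
   maximum by walking to the nearest zero transitions.

Step 3 is what removes the classical requirement of a motor-enforced
constant angular velocity: two recordings of the same torque-versus-angle
relationship at different (even varying) cadences give the same template
profile up to interpolation error, which is the property the
`cadence invariance` tests assert.

Two control signals are supported. The *crank angle* (0° = right crank arm
vertically down, increasing clockwise seen from the right) is shared by
both legs. The *cycling phase* is a per-leg normalization of the
IMU-measured thigh angle: within each flexion–extension–flexion cycle,
extension maps to 0–50 % and flexion to 50–100 %, using the extrema of the
most recently completed cycle as the normalization anchors (the first
cycle uses its own extrema retrospectively).

## From interval to real-time commands

An interval detected at 5 RPM cannot be replayed verbatim at a riding
cadence of 50–60 RPM: by the time a sensor reports a position the crank
has moved on, and the muscle needs time to build force. Stimulation must
therefore start earlier by

$$\mathrm{Shift}_{START} = \frac{\mathrm{Delay}_{Muscle} +
\mathrm{Delay}_{Sensor}}{\mathrm{Duration}_{Cycle}} \times 360°$$

and stop earlier by

$$\mathrm{Shift}_{STOP} = \frac{\mathrm{Delay}_{Sensor}}
{\mathrm{Duration}_{Cycle}} \times 360°,$$

both re-evaluated once per cycle from the duration of the most recently
completed cycle. The same time-to-position reasoning is applied to the
phase domain with 100 % substituted for 360°. `compensate_interval()`
implements the shifts, `stimulation_command()` / `replay_session()` the
per-sample on/off decision, with half-open membership `[start, stop)` so
adjacent complementary intervals never double-fire at a shared boundary.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `target_cadence_rpm` | 5 | RPM | examiner's target during fitting |
| `cadence_tolerance` | 0.5 | – | gate half-width; 5 RPM ± 50 % ⇒ accept 2.5–7.5 RPM, bounds inclusive |
| `n_cycles` | 3 | – | accepted cycles averaged per segment |
| `sensor_crank_ms` | 200 | ms | power-meter transmission latency (angle and torque share it) |
| `sensor_imu_ms` | 40 | ms | IMU filter latency |
| `muscle_ms` | 200 | ms | electromechanical delay used by the start shift |
| `grid_hz` | 100 | Hz | processing rate of alignment and replay |
| `max_gap_bins` | 20 | bins | largest tolerated hole in position coverage of one cycle |
| `min_range_deg` | 10 | deg | smallest thigh excursion accepted as motion |

`n_cycles` counts *accepted* cycles: because the first accepted active
cycle is always discarded, a recording must contain at least
`n_cycles + 1` accepted active cycles. With the phase signal the cycle
boundaries (flexion extrema) are offset from the crank revolutions and the
stream needs a warm-up extremum, so budget roughly one extra revolution at
each end of both segments for that modality.

## The simulator: what it emulates, and what it does not

`simulate_session()` generates the raw multichannel log of a fitting
session with known ground truth, which is what makes the whole pipeline
testable without hardware or subjects. It is a *phenomenological* model:

* **kinematics** — piecewise-constant cadence per revolution, drawn
  uniformly from `target × (1 ± jitter)`; thigh angles are
  `offset + amplitude·cos(crank − ψ_side)` with the two sides 180° apart,
  so phase cycles align consistently with crank revolutions;
* **passive torque** — a zero-mean sum of the first two crank harmonics
  per side (legs mounted 180° apart), the shape a leg's weight produces;
* **muscle contribution** — a raised-cosine (Tukey) plateau bump that is
  strictly positive exactly on the configured true interval and zero
  outside it. The taper width defaults to 3 % of the span (≈ 11° / 3 %):
  the rise distance of a stimulated muscle is governed by its
  electromechanical delay (≈ 200–300 ms, i.e. 6–10° at 5 RPM) and does
  not grow with the width of the contribution region, so the edge
  steepness is deliberately width-independent. An optional negative lobe
  outside the interval mimics the eccentric resisting phase, which in
  practice exceeds the concentric contribution;
* **sensors** — the emitted power-meter channels report the physical state
  200 ms earlier and the IMU channels 40 ms earlier (configurable), so
  `align_streams()` genuinely has to undo them; Gaussian measurement noise
  is added per torque sample; the whole stream is deterministic under its
  seed.

Because crank angle and torque travel in the *same* power-meter packet,
ignoring their shared latency leaves the torque-versus-angle relationship
— and hence the detected interval — unchanged for the crank modality; the
suite asserts this cancellation. Alignment still matters wherever two
differently-delayed streams meet: the phase modality pairs IMU positions
with power-meter torque, and the stimulation-state flags are on the
command clock.

The simulator does **not** model muscle fatigue, recruitment curves,
rider–trike dynamics under load, or IMU drift. Passing tests therefore
show that the algorithm recovers intervals from data of the assumed
structure (smooth passive torque, additive positionally-fixed
contribution, white torque noise); they cannot certify behaviour under
structured artefacts real sessions may contain.

## Numerical choices

* **Interpolation** is linear everywhere (time-to-grid alignment and
  position-to-template normalization), the simplest scheme consistent
  with 50→100 Hz upsampling; angles are unwrapped before and re-wrapped
  after, so nothing interpolates across the 360→0 seam.
* **Zero transitions.** The interval search treats a bin as positive only
  above a tolerance of `1e-4` of the largest absolute net-torque value.
  Template resampling of the passive and active means leaves ±1e-5-scale
  round-off where the true net torque is exactly zero; a strict sign test
  would extend the detected run through such bins. The tolerance is far
  below any physical torque and can be set to 0 for exact comparisons
  (the brute-force-oracle tests do).
* **Cycle boundaries** fire at the interpolated upward crossing of the
  origin (0° or phase 100→0), and boundary levels are consumed
  monotonically — after one boundary the next expected level is a full
  period higher — so brief backward jitter can never split a revolution.
  A stream starting exactly on the origin counts as a boundary.
* **Ties** at the net-torque maximum break toward the first maximal bin
  scanning upward from 0; bin 0 and bin `span` are tied (averaged) after
  interpolation so the profile is single-valued on the circle.
* **Degenerate inputs.** No positive bin ⇒ a no-positive-contribution
  error (the muscle never helps); all bins positive ⇒ an explicit
  full-cycle interval; thigh excursion below `min_range_deg` ⇒ a
  degenerate-motion error; a compensated width reaching the span ⇒
  saturation to full-cycle with a warning.
* **Phase cold start.** The extremum tracker needs a direction reversal
  of at least `min_range_deg / 2` before it trusts an extremum, and a
  "flexion extremum" coinciding with the first sample whose value is far
  from the later flexion extrema is treated as a mid-limb stream start and
  its partial cycle dropped.

## Design choices that were genuinely open

* The recorded log has no live protocol, so the passive/active split comes
  from `stim_on` flags when present, else an explicit `split_t_ms`.
* Whether the quoted "3 active cycles" include the rejected first cycle is
  ambiguous in the source protocol; here `n_cycles` means cycles that
  *enter the average*, and the rejection consumes one extra.
* Interval endpoints are reported at integer bin resolution (matching how
  patterns are tabulated in practice); no sub-bin interpolation of the
  zero crossing is attempted.
* No smoothing is applied to the net torque before the search by default;
  a circular moving-average window (`smooth_window`) exists for noisy
  field data but all reported results use the raw profile.
* The alignment drops the uncovered tail (up to the largest delay) rather
  than extrapolating.

## Problem sizes

The test-suite and the acceptance script size their simulations as a full
study would: 56 noiseless sessions spanning interval widths 40–320°
(including wrap-around placements) at 3–7 RPM, 200 noisy sessions at a
torque-noise standard deviation of 10 % of the 5 N·m contribution peak,
1000 random profiles and 1000 random intervals against the brute-force
oracles, and 500 random delay/duration draws against the closed-form
shifts.

## A worked example

```{r example}
set.seed(1)
s <- simulate_session(simulation_config(
  true_interval = stim_interval(259, 68), noise_sd_nm = 0.25, seed = 14))
fit <- oida(s, session_config(), delay_model())
fit
coef(fit)
```

```{r plot}
plot(fit, main = "Averaged torque profiles and detected interval")
```

At a riding cadence of 55 RPM the compensated command interval is:

```{r compensate}
compensate_interval(fit$interval, delay_model(), 60000 / 55)
```

## Known limitations

* Validated against synthetic data only; the algorithm is deliberately
  identical for real logs, but sensor drop-outs, IMU drift and
  non-stationary fatigue are outside the simulator's scope.
* The phase modality assumes the thigh oscillates once per crank
  revolution; free-wheeling or reversals violate the segmentation
  preconditions.
* Per-cycle power in `summarize_session()` derives angular velocity from
  finite differences of the crank angle, which is noisier than a power
  meter's internal estimate.
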