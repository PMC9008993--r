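# oida

Optimal stimulation-interval detection for FES-cycling.

In functional electrical stimulation (FES) cycling, people with spinal
cord injury pedal a trike by electrical activation of their paralyzed leg
muscles. Performance depends on stimulating each muscle channel only over
the part of the pedalling cycle where it propels the crank. This package
determines those intervals from data instead of manual trial and error:
during a short fitting session an examiner turns the rider's legs slowly
(≈5 RPM) while an instrumented crank logs per-side torque, first without
and then with continuous stimulation. The per-muscle stimulation interval
is read off the **net torque**

> net(θ) = mean active torque(θ) − mean passive torque(θ)

on a fixed position template (crank angle 0–360° in 1° bins, or the
IMU-derived cycling phase 0–100 % in 1 % bins): the detected interval is
the run of positive net torque containing its maximum, found by walking
from the maximal bin to the nearest zero transitions. Because cycles are
resampled by *position*, no motor-enforced constant angular velocity is
needed — the method works on mobile systems.

For riding cadences the interval is delay-compensated per cycle:

    Shift_START = (Delay_Muscle + Delay_Sensor) / Duration_Cycle × 360°
    Shift_STOP  =  Delay_Sensor                 / Duration_Cycle × 360°

with defaults of 200 ms (power-meter transmission), 40 ms (IMU filtering)
and 200 ms (muscle electromechanical delay). A built-in pedalling
simulator with known ground-truth contribution intervals makes the whole
pipeline testable end to end without hardware.

## Worked example

```r
library(oida)

# a synthetic fitting session: left quadriceps, ground truth 259° -> 68°,
# 3 passive + 4 active cycles at 5 RPM, realistic sensor delays and noise
s <- simulate_session(simulation_config(
  true_interval = stim_interval(259, 68), noise_sd_nm = 0.25, seed = 14))

fit <- oida(s, session_config(), delay_model())
fit
#> Optimal stimulation interval detection
#>   channel      LQ (left leg), control signal: crank
#>   cycles used  3 passive + 3 active (first active rejected)
#>   interval     260° → 67° (wraps through 0)
#>   peak net     5.71 N·m at 274 deg
coef(fit)
#> start  stop
#>   260    67
```

The detected interval recovers the simulated truth within one template
bin: the muscle should be on from 260° through the top-dead-centre wrap to
67°, and the net torque peaks at 5.71 N·m near 274°. `plot(fit)` draws the
averaged passive/active/net profiles with the interval shaded;
`summary(fit)` adds the per-cycle cadences and accept/reject diagnostics.

At a riding cadence of 55 RPM (1091 ms cycles) the real-time command
interval starts earlier by the muscle-plus-sensor shift and stops earlier
by the sensor shift:

```r
compensate_interval(fit$interval, delay_model(), 60000 / 55)
#> <stim_interval> 128° → 1° (wraps through 0)
```

(start shift 132.0°, stop shift 66.0°). `replay_session()` turns a logged
session plus a pattern into the per-sample on/off command stream, and
`summarize_session()` reports duration, distance, speed, cadence and
power of a recorded ride.

A thin command-line front end ships in `exec/oida`:

```sh
Rscript exec/oida simulate --out session.csv --seed 3
Rscript exec/oida detect --input session.csv --signal crank --out pattern.json
Rscript exec/oida compensate --pattern pattern.json --cadence 55
```

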