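# Synthetic pedalling sessions with known ground truth.
#
# The simulator is a phenomenological torque model: the detection pipeline
# consumes only torque-versus-position, so a gravity-dominated passive
# torque plus an additive stimulated-muscle contribution that is positive
# exactly on a configurable interval is the minimal structure exercising
# every code path (no musculoskeletal model is attempted).

#' Configuration of a simulated interval-detection session
#'
#' Defaults emulate the reference measurement protocol: slow
#' manually-assisted pedalling at 5 RPM with a 50 % cadence gate, 3 passive
#' cycles followed by continuous stimulation (4 active cycles, so 3 remain
#' after the first is rejected), power-meter channels delayed by 200 ms and
#' IMU channels by 40 ms, sampled at 100 Hz.
#'
#' @param true_interval ground-truth contribution interval
#'   ([stim_interval()]); its span must match `domain`.
#' @param channel stimulated muscle channel (determines which torque side
#'   carries the contribution).
#' @param domain control-signal domain the truth is expressed in:
#'   `"crank"` (deg) or `"phase"` (IMU cycling phase, %).
#' @param passive passive (gravity) torque model parameters, see
#'   [passive_torque_model()].
#' @param peak_nm peak of the muscle contribution bump, N·m.
#' @param taper taper width of the contribution bump in domain units
#'   (default 3 % of the span, roughly the distance the crank travels
#'   during the muscle's electromechanical rise at the recording cadence);
#'   clipped to half the interval width.
#' @param neg_peak_nm optional peak of a negative (eccentric, resisting)
#'   lobe outside the interval; 0 disables it.
#' @param target_cadence_rpm,cadence_jitter cadence profile: each cycle's
#'   cadence is drawn uniformly from target * (1 +/- jitter).
#' @param noise_sd_nm additive Gaussian measurement noise on both torque
#'   channels, per sample, N·m.
#' @param delays sensor/muscle [delay_model()]; sensor delays are APPLIED
#'   to the emitted streams (a logged sample reports the physical state one
#'   sensor latency earlier), so [align_streams()] must undo them.
#' @param muscle_lag_ms activation rise time after stimulation onset; the
#'   contribution ramps in linearly over this time at the start of the
#'   active segment (the onset transient confined to the first active
#'   cycle).
#' @param n_passive,n_active number of simulated passive/active
#'   revolutions.
#' @param sample_hz emission rate of the combined log.
#' @param lead_ms,tail_ms extra motion before the first and after the last
#'   counted revolution, so that sensor-delay alignment and partial-cycle
#'   trimming do not consume counted cycles.
#' @param thigh thigh-angle model: `offset_deg + amplitude_deg *
#'   cos(crank - phase_<side>_deg)` per side, sides 180 deg apart; with the
#'   default mounting, decreasing thigh angle is knee extension.
#' @param seed integer; fixes the full output stream.
#' @return an object of class `"simulation_config"`.
#' @export
simulation_config <- function(true_interval = stim_interval(259, 68),
                              channel = "LQ",
                              domain = c("crank", "phase"),
                              passive = list(a1 = 2, phi1 = 0, a2 = 0.5,
                                             phi2 = 0, offset = 0),
                              peak_nm = 5,
                              taper = NULL,
                              neg_peak_nm = 0,
                              target_cadence_rpm = 5,
                              cadence_jitter = 0.1,
                              noise_sd_nm = 0,
                              delays = delay_model(),
                              muscle_lag_ms = 200,
                              n_passive = 3, n_active = 4,
                              sample_hz = 100,
                              lead_ms = 1000, tail_ms = 1000,
                              thigh = list(offset_deg = 20, amplitude_deg = 25,
                                           phase_left_deg = 0,
                                           phase_right_deg = 180),
                              seed = 1L) {
  domain <- match.arg(domain)
  span <- domain_span(domain)
  stopifnot(inherits(true_interval, "stim_interval"),
            inherits(delays, "delay_model"))
  if (true_interval$span != span) {
    oida_abort("true_interval span does not match the domain",
               "oida_config_error")
  }
  if (n_passive < 1 || n_active < 1) {
    oida_abort("n_passive and n_active must be >= 1", "oida_config_error")
  }
  if (noise_sd_nm < 0) oida_abort("noise_sd_nm must be >= 0", "oida_config_error")
  taper <- taper %||% (0.03 * span)
  structure(list(true_interval = true_interval, channel = channel,
                 domain = domain, passive = passive, peak_nm = peak_nm,
                 taper = taper, neg_peak_nm = neg_peak_nm,
                 target_cadence_rpm = target_cadence_rpm,
                 cadence_jitter = cadence_jitter,
                 noise_sd_nm = noise_sd_nm, delays = delays,
                 muscle_lag_ms = muscle_lag_ms,
                 n_passive = as.integer(n_passive),
                 n_active = as.integer(n_active),
                 sample_hz = sample_hz, lead_ms = lead_ms, tail_ms = tail_ms,
                 thigh = thigh, seed = seed),
            class = "simulation_config")
}

#' Passive (gravity-dominated) crank torque
#'
#' Smooth periodic function of the crank angle: the sum of the first two
#' harmonics plus a constant offset,
#' `a1 sin(theta - phi1) + a2 sin(2 (theta - phi2)) + offset`.
#' With zero offset the torque integrates to zero over a revolution, as a
#' purely gravitational leg-weight torque must.
#'
#' @param theta_deg crank angle(s) in degrees.
#' @param params list with `a1`, `phi1`, `a2`, `phi2`, `offset`
#'   (amplitudes in N·m, phases in degrees).
#' @return torque in N·m.
#' @export
passive_torque_model <- function(theta_deg,
                                 params = list(a1 = 2, phi1 = 0, a2 = 0.5,
                                               phi2 = 0, offset = 0)) {
  r <- pi / 180
  params$a1 * sin((theta_deg - params$phi1) * r) +
    params$a2 * sin(2 * (theta_deg - params$phi2) * r) +
    params$offset
}

#' Stimulated-muscle torque contribution
#'
#' A raised-cosine (Tukey) plateau bump: zero outside the (optionally
#' shifted) true interval, strictly positive everywhere inside it, rising
#' from the start over `taper` domain units, flat at `peak`, and falling
#' over the last `taper` units. The taper is clipped to half the interval
#' width (a narrow interval degenerates to a pure raised cosine). An
#' optional negative lobe over the complement of the interval mimics the
#' eccentric resisting phase.
#'
#' @param position position(s) in domain units.
#' @param true_interval a [stim_interval()].
#' @param peak_nm bump peak, N·m.
#' @param taper taper width in domain units.
#' @param shift rotation applied to the interval (domain units; models an
#'   activation lag expressed in position).
#' @param neg_peak_nm peak of the negative lobe (0 disables).
#' @return torque in N·m.
#' @export
active_contribution <- function(position, true_interval, peak_nm = 5,
                                taper = 0.03 * true_interval$span,
                                shift = 0, neg_peak_nm = 0) {
  stopifnot(inherits(true_interval, "stim_interval"))
  span <- true_interval$span
  if (true_interval$full_cycle) return(rep(peak_nm, length(position)))
  w <- interval_width(true_interval)
  tp <- min(taper, w / 2)
  d <- (position - (true_interval$start + shift)) %% span
  env <- ifelse(d <= 0 | d >= w, 0,
                ifelse(d < tp, 0.5 * (1 - cos(pi * d / tp)),
                       ifelse(d > w - tp, 0.5 * (1 - cos(pi * (w - d) / tp)),
                              1)))
  out <- peak_nm * env
  if (neg_peak_nm > 0) {
    wn <- span - w
    dn <- (position - (true_interval$stop + shift)) %% span
    neg <- ifelse(dn <= 0 | dn >= wn, 0,
                  0.5 * (1 - cos(2 * pi * dn / wn)))
    out <- out - neg_peak_nm * neg
  }
  out
}

# closed-form cycling phase of the simulated thigh trajectory:
# thigh = offset + amp * cos(u - psi)  =>  flexion extremum at u = psi,
# extension half  phase = 25 (1 - cos(u - psi)),
# flexion  half  phase = 50 + 25 (1 + cos(u - psi)).
simulated_phase <- function(u_deg, psi_deg) {
  x <- wrap_angle(u_deg - psi_deg, 360)
  r <- pi / 180
  ifelse(x < 180, 25 * (1 - cos(x * r)), 50 + 25 * (1 + cos(x * r)))
}

#' Simulate a full interval-detection session
#'
#' Generates the raw multichannel log of one measurement: a lead-in, then
#' `n_passive` unstimulated revolutions, then continuous stimulation for
#' `n_active` revolutions, then a tail. The crank moves at a
#' constant-within-cycle cadence drawn per cycle from the jitter band; the
#' thigh angles are consistent periodic functions of the crank angle (so
#' phase cycles align with crank revolutions); torque is passive gravity
#' torque plus, during stimulation, the muscle contribution on the
#' configured channel, plus measurement noise. Sensor delays are applied to
#' the emitted streams: a logged power-meter sample reports the state
#' 200 ms earlier, an IMU sample 40 ms earlier (defaults), so
#' [align_streams()] must undo them. `stim_on` flags the stimulation
#' command state (no sensor latency). Deterministic under `seed`.
#'
#' @param config a [simulation_config()].
#' @return a [sensor_frames()] stream with attribute `"truth"`: a list with
#'   the ground-truth `interval`, stimulation onset `t_on_ms`, per-cycle
#'   `cadences_rpm` and the `config`.
#' @export
simulate_session <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_cyc <- cfg$n_passive + cfg$n_active
    cad <- cfg$target_cadence_rpm *
      (1 + cfg$cadence_jitter * stats::runif(n_cyc, -1, 1))
    durs <- 60000 / cad
    rate1 <- 360 / durs[1L]
    raten <- 360 / durs[n_cyc]
    knot_t <- c(0, cfg$lead_ms, cfg$lead_ms + cumsum(durs),
                cfg$lead_ms + sum(durs) + cfg$tail_ms)
    knot_u <- c(-cfg$lead_ms * rate1, 0, (1:n_cyc) * 360,
                n_cyc * 360 + cfg$tail_ms * raten)
    total <- knot_t[length(knot_t)]
    step <- 1000 / cfg$sample_hz
    t <- seq(0, total, by = step)
    theta_at <- function(tt) stats::approx(knot_t, knot_u, xout = tt,
                                           rule = 2)$y
    t_on <- cfg$lead_ms + sum(durs[seq_len(cfg$n_passive)])

    side <- muscle_side(cfg$channel)
    if (is.na(side)) {
      oida_abort("simulator channel must name a side (L*/R*)",
                 "oida_config_error")
    }
    psi <- c(left = cfg$thigh$phase_left_deg,
             right = cfg$thigh$phase_right_deg)
    torque_phys <- function(tt) {
      u <- theta_at(tt)
      # each leg's pedal sits opposite the reference (right) crank arm
      pl <- passive_torque_model(u + 180, cfg$passive)
      pr <- passive_torque_model(u, cfg$passive)
      envel <- pmin(pmax((tt - t_on) /
                           max(cfg$muscle_lag_ms, .Machine$double.eps), 0), 1)
      pos <- if (cfg$domain == "crank") wrap_angle(u, 360)
             else simulated_phase(u, psi[[side]])
      bump <- envel * active_contribution(pos, cfg$true_interval,
                                          cfg$peak_nm, cfg$taper,
                                          neg_peak_nm = cfg$neg_peak_nm)
      if (side == "left") pl <- pl + bump else pr <- pr + bump
      list(left = pl, right = pr)
    }

    tq <- torque_phys(t - cfg$delays$sensor_crank_ms)
    u_pm <- theta_at(t - cfg$delays$sensor_crank_ms)
    u_imu <- theta_at(t - cfg$delays$sensor_imu_ms)
    r <- pi / 180
    frames <- data.frame(
      t_ms = t,
      crank_angle_deg = wrap_angle(u_pm, 360),
      torque_left_nm = tq$left +
        stats::rnorm(length(t), 0, cfg$noise_sd_nm),
      torque_right_nm = tq$right +
        stats::rnorm(length(t), 0, cfg$noise_sd_nm),
      thigh_left_deg = cfg$thigh$offset_deg +
        cfg$thigh$amplitude_deg * cos((u_imu - psi[["left"]]) * r),
      thigh_right_deg = cfg$thigh$offset_deg +
        cfg$thigh$amplitude_deg * cos((u_imu - psi[["right"]]) * r),
      stim_on = as.integer(t >= t_on))
    out <- sensor_frames(frames)
    attr(out, "truth") <- list(interval = cfg$true_interval, t_on_ms = t_on,
                               cadences_rpm = cad, config = cfg)
    out
  })
}
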