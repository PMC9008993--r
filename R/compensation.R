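# Cadence-dependent delay compensation, the per-sample stimulation command,
# and stimulation-pattern I/O.

#' Start-shift for cadence-dependent delay compensation
#'
#' To have the muscle active at the detected positions despite sensor
#' transmission latency and the muscle's electromechanical delay,
#' stimulation must start earlier than the detected interval by
#' `(delay_muscle + delay_sensor) / duration_cycle * span` domain units
#' (`span` = 360 deg for the crank domain; the same time-to-position
#' reasoning with `span` = 100 applies to the phase domain).
#'
#' @param delays a [delay_model()].
#' @param duration_ms duration of the current cycle in ms (> 0).
#' @param span domain span (360 or 100).
#' @param signal which sensor feeds the control signal: `"crank"` or
#'   `"phase"`; selects the sensor delay.
#' @return shift in domain units (>= 0).
#' @export
shift_start <- function(delays, duration_ms, span = 360,
                        signal = c("crank", "phase")) {
  signal <- match.arg(signal)
  stopifnot(inherits(delays, "delay_model"))
  if (!is.numeric(duration_ms) || any(duration_ms <= 0)) {
    oida_abort("duration_ms must be > 0", "oida_domain_error")
  }
  (delays$muscle_ms + sensor_delay(delays, signal)) / duration_ms * span
}

#' Stop-shift for cadence-dependent delay compensation
#'
#' Stopping stimulation only needs to compensate the sensor delay (the
#' muscle relaxing late is the desired behaviour at the interval end):
#' `delay_sensor / duration_cycle * span`.
#'
#' @param delays a [delay_model()] or a bare numeric sensor delay in ms.
#' @inheritParams shift_start
#' @return shift in domain units (>= 0).
#' @export
shift_stop <- function(delays, duration_ms, span = 360,
                       signal = c("crank", "phase")) {
  signal <- match.arg(signal)
  if (!is.numeric(duration_ms) || any(duration_ms <= 0)) {
    oida_abort("duration_ms must be > 0", "oida_domain_error")
  }
  ds <- if (inherits(delays, "delay_model")) sensor_delay(delays, signal)
        else as.numeric(delays)
  stopifnot(is.numeric(ds), ds >= 0)
  ds / duration_ms * span
}

#' Apply delay compensation to a stimulation interval
#'
#' Shifts both endpoints earlier in the cycle: the start by
#' [shift_start()], the stop by [shift_stop()] (both modulo the span).
#' Because the start shift is at least the stop shift, compensation widens
#' the interval; if the compensated width reaches the full span (e.g. at a
#' cycle duration so short that the start shift exceeds the span), the
#' interval saturates to full-cycle and a warning is raised.
#'
#' @param interval a [stim_interval()].
#' @param delays a [delay_model()].
#' @param duration_ms current cycle duration in ms.
#' @param signal control-signal kind; default inferred from the interval's
#'   span (360 -> `"crank"`, 100 -> `"phase"`).
#' @return an object of class `c("compensated_interval", "stim_interval")`
#'   with extra fields `source`, `shift_start`, `shift_stop`.
#' @export
compensate_interval <- function(interval, delays, duration_ms,
                                signal = NULL) {
  stopifnot(inherits(interval, "stim_interval"),
            inherits(delays, "delay_model"))
  span <- interval$span
  signal <- signal %||% if (span == 360) "crank" else "phase"
  s1 <- shift_start(delays, duration_ms, span, signal)
  s2 <- shift_stop(delays, duration_ms, span, signal)
  saturated <- s1 >= span ||
    (!interval$full_cycle && interval_width(interval) + (s1 - s2) >= span)
  out <- if (interval$full_cycle || saturated) {
    stim_interval(0, 0, span, full_cycle = TRUE)
  } else {
    stim_interval((interval$start - s1) %% span,
                  (interval$stop - s2) %% span, span)
  }
  if (saturated && !interval$full_cycle) {
    oida_warn(sprintf(
      "compensated interval saturates to full cycle (width %.1f + shift %.1f >= span %g)",
      interval_width(interval), s1 - s2, span), "oida_saturation_warning")
  }
  out$source <- interval
  out$shift_start <- s1
  out$shift_stop <- s2
  class(out) <- c("compensated_interval", class(out))
  out
}

#' Stimulation pattern: one interval per muscle channel
#'
#' @param ... named arguments, one per channel, each either a
#'   [stim_interval()] (the side is then inferred from the channel name) or
#'   a list with fields `interval` and `side`.
#' @return an object of class `"stim_pattern"`.
#' @examples
#' stim_pattern(LQ = stim_interval(259, 68), RQ = stim_interval(72, 255))
#' @export
stim_pattern <- function(...) {
  entries <- list(...)
  if (length(entries) == 0L) {
    oida_abort("pattern must contain at least one channel", "oida_config_error")
  }
  if (is.null(names(entries)) || any(names(entries) == "")) {
    oida_abort("pattern entries must be named by channel", "oida_config_error")
  }
  out <- lapply(names(entries), function(ch) {
    e <- entries[[ch]]
    if (inherits(e, "stim_interval")) {
      e <- list(interval = e, side = muscle_side(ch))
    }
    stopifnot(inherits(e$interval, "stim_interval"))
    if (is.na(e$side %||% NA_character_)) {
      oida_abort(sprintf("cannot infer side for channel '%s'; supply it", ch),
                 "oida_config_error")
    }
    e[c("interval", "side")]
  })
  names(out) <- names(entries)
  structure(out, class = "stim_pattern")
}

#' @export
print.stim_pattern <- function(x, ...) {
  cat("<stim_pattern>\n")
  for (ch in names(x)) {
    cat(sprintf("  %-4s (%s): %s\n", ch, x[[ch]]$side,
                format(x[[ch]]$interval)))
  }
  invisible(x)
}

#' Write a stimulation pattern to JSON
#'
#' Per-muscle schema: `domain`, `start`, `stop`, `full_cycle`, `n_cycles`,
#' `generated_at`.
#'
#' @param pattern a [stim_pattern()].
#' @param path output path.
#' @param n_cycles cycles averaged during detection (recorded as metadata).
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pattern, path, n_cycles = NA_integer_) {
  stopifnot(inherits(pattern, "stim_pattern"))
  lst <- lapply(pattern, function(e) {
    iv <- e$interval
    list(domain = if (iv$span == 360) "crank" else "phase",
         side = e$side,
         start = iv$start, stop = iv$stop, full_cycle = iv$full_cycle,
         n_cycles = n_cycles,
         generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a stimulation pattern from JSON
#' @param path path written by [write_pattern()].
#' @return a [stim_pattern()].
#' @export
read_pattern <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- lapply(lst, function(e) {
    span <- if (identical(e$domain, "phase")) 100 else 360
    list(interval = stim_interval(e$start, e$stop, span,
                                  full_cycle = isTRUE(e$full_cycle)),
         side = e$side)
  })
  do.call(stim_pattern, args)
}

#' Per-sample stimulation on/off decision
#'
#' For each channel of the pattern the current position of its control
#' signal is tested against the delay-compensated interval for the current
#' cycle-duration estimate.
#'
#' @param positions named list of current positions: `crank` (deg) and/or
#'   `phase_left`, `phase_right` (%), as required by the pattern's domains.
#'   Each element may be a vector (positions are evaluated element-wise).
#' @param pattern a [stim_pattern()].
#' @param delays a [delay_model()].
#' @param cadence_rpm running cadence estimate (> 0), typically the cadence
#'   of the most recently completed cycle.
#' @param compensate apply delay compensation (`FALSE` reproduces raw
#'   interval membership).
#' @return named logical matrix, one column per channel.
#' @export
stimulation_command <- function(positions, pattern, delays, cadence_rpm,
                                compensate = TRUE) {
  stopifnot(inherits(pattern, "stim_pattern"), is.numeric(cadence_rpm),
            cadence_rpm > 0)
  duration <- 60000 / cadence_rpm
  cols <- lapply(names(pattern), function(ch) {
    e <- pattern[[ch]]
    iv <- e$interval
    key <- if (iv$span == 360) "crank" else paste0("phase_", e$side)
    pos <- positions[[key]]
    if (is.null(pos)) {
      oida_abort(sprintf(
        "no '%s' position signal supplied for channel '%s'", key, ch),
        "oida_config_error")
    }
    use <- if (compensate) {
      compensate_interval(iv, delays, duration,
                          signal = if (iv$span == 360) "crank" else "phase")
    } else iv
    in_interval(pos, use)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- names(pattern)
  out
}

#' Replay a logged session against a stimulation pattern
#'
#' Emits the per-sample stimulation command the controller would have
#' produced: streams are delay-aligned, the cycle-duration estimate is the
#' duration of the most recently completed cycle (before the first
#' completed cycle, the configured expected cadence), and shifts are
#' re-evaluated once per cycle.
#'
#' @param frames raw [sensor_frames()].
#' @param pattern a [stim_pattern()].
#' @param delays a [delay_model()].
#' @param expected_cadence_rpm fallback cadence estimate before the first
#'   cycle completes.
#' @param grid_hz processing rate.
#' @param compensate apply delay compensation.
#' @return data frame: `t_ms`, the position signals used, and one logical
#'   command column per channel (named `cmd_<channel>`).
#' @export
replay_session <- function(frames, pattern, delays = delay_model(),
                           expected_cadence_rpm = 30, grid_hz = 100,
                           compensate = TRUE) {
  stopifnot(inherits(pattern, "stim_pattern"))
  al <- align_streams(frames, delays, grid_hz)
  t <- al$t_ms
  spans <- vapply(pattern, function(e) e$interval$span, numeric(1L))
  positions <- list()
  if (any(spans == 360)) positions$crank <- al$crank_angle_deg
  for (sd in unique(vapply(pattern[spans == 100], `[[`, character(1L), "side"))) {
    ph <- compute_cycling_phase(al, side = sd)
    positions[[paste0("phase_", sd)]] <-
      stats::approx(ph$t_ms, ph$phase, xout = t, rule = 2)$y
  }
  # once-per-cycle cadence estimate from crank revolutions
  cycles <- detect_crank_cycles(al)
  cad <- rep(expected_cadence_rpm, length(t))
  if (length(cycles)) {
    ends <- vapply(cycles, `[[`, numeric(1L), "end_t")
    cads <- vapply(cycles, `[[`, numeric(1L), "cadence_rpm")
    k <- findInterval(t, ends)  # 0 before first completed cycle
    cad[k > 0] <- cads[k[k > 0]]
  }
  out <- data.frame(t_ms = t)
  for (key in names(positions)) out[[key]] <- positions[[key]]
  cmd <- matrix(FALSE, nrow = length(t), ncol = length(pattern))
  colnames(cmd) <- names(pattern)
  for (cv in unique(cad)) {
    rows <- which(cad == cv)
    cmd[rows, ] <- stimulation_command(
      lapply(positions, `[`, rows), pattern, delays, cv,
      compensate = compensate)
  }
  for (ch in names(pattern)) out[[paste0("cmd_", ch)]] <- cmd[, ch]
  out
}

#' Session performance summary
#'
#' Descriptive statistics of a cycling session: duration, distance from
#' wheel-revolution events, average/maximum speed, per-cycle cadence and
#' per-cycle power (mean over the cycle of total crank torque times angular
#' velocity, the latter by finite differences of the unwrapped crank angle).
#'
#' @param frames a [sensor_frames()] stream (raw or aligned; torque and
#'   angle are paired row-wise).
#' @param wheel_circumference_m wheel circumference in metres (needed for
#'   distance/speed).
#' @return an object of class `"session_summary"` with fields
#'   `duration_s`, `duration` (mm:ss), `distance_m`, `speed_avg_kmh`,
#'   `speed_max_kmh`, `cadence_avg_rpm`, `cadence_max_rpm`, `power_avg_w`,
#'   `power_max_w`. Distance and speeds are `NA` (reported unavailable, not
#'   zero) when no wheel-revolution channel or circumference is supplied.
#' @export
summarize_session <- function(frames, wheel_circumference_m = NULL) {
  frames <- sensor_frames(frames)
  t <- frames$t_ms
  duration_s <- (t[length(t)] - t[1L]) / 1000
  distance_m <- speed_avg <- speed_max <- NA_real_
  if (!is.null(wheel_circumference_m) && "wheel_rev" %in% names(frames)) {
    nrev <- sum(frames$wheel_rev)
    distance_m <- nrev * wheel_circumference_m
    speed_avg <- if (duration_s > 0) distance_m / duration_s * 3.6 else 0
    te <- t[frames$wheel_rev >= 1]
    speed_max <- if (length(te) >= 2L) {
      max(wheel_circumference_m / (diff(te) / 1000)) * 3.6
    } else if (nrev == 0) 0 else NA_real_
  }
  cycles <- detect_crank_cycles(frames)
  if (length(cycles)) {
    cads <- vapply(cycles, `[[`, numeric(1L), "cadence_rpm")
    pows <- vapply(cycles, function(cy) {
      d <- cy$data
      if (nrow(d) < 2L) return(NA_real_)
      omega <- diff(d$pos) / diff(d$t_ms) * (pi / 180) * 1000  # rad/s
      tq <- (d$torque_left_nm + d$torque_right_nm)
      mean((tq[-1L] + tq[-nrow(d)]) / 2 * omega)
    }, numeric(1L))
    cadence_avg <- mean(cads); cadence_max <- max(cads)
    power_avg <- mean(pows); power_max <- max(pows)
  } else {
    cadence_avg <- cadence_max <- power_avg <- power_max <- NA_real_
  }
  structure(list(duration_s = duration_s,
                 duration = format_mmss(duration_s),
                 distance_m = distance_m,
                 speed_avg_kmh = speed_avg, speed_max_kmh = speed_max,
                 cadence_avg_rpm = cadence_avg, cadence_max_rpm = cadence_max,
                 power_avg_w = power_avg, power_max_w = power_max),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.2f", v)
  cat("<session_summary>\n")
  cat(sprintf("  duration  %s (%.1f s)\n", x$duration, x$duration_s))
  cat(sprintf("  distance  %s m\n", fmt(x$distance_m)))
  cat(sprintf("  speed     avg %s / max %s km/h\n",
              fmt(x$speed_avg_kmh), fmt(x$speed_max_kmh)))
  cat(sprintf("  cadence   avg %s / max %s RPM\n",
              fmt(x$cadence_avg_rpm), fmt(x$cadence_max_rpm)))
  cat(sprintf("  power     avg %s / max %s W\n",
              fmt(x$power_avg_w), fmt(x$power_max_w)))
  invisible(x)
}
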