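# Sensor-log I/O, configuration objects and delay alignment.
#
# The CSV dialect is fixed: comma separated, dot decimal, one header row,
# time in milliseconds from session start. Mandatory columns:
#   t_ms, crank_angle_deg, torque_left_nm, torque_right_nm,
#   thigh_left_deg, thigh_right_deg
# Optional columns: stim_on (0/1 stimulation command state), wheel_rev
# (1 on rows carrying a wheel-revolution event, else 0).

.cols_required <- c("t_ms", "crank_angle_deg", "torque_left_nm",
                    "torque_right_nm", "thigh_left_deg", "thigh_right_deg")
.cols_optional <- c("stim_on", "wheel_rev")
.cols_power <- c("crank_angle_deg", "torque_left_nm", "torque_right_nm")
.cols_imu <- c("thigh_left_deg", "thigh_right_deg")

#' Validate a multichannel sensor-frame stream
#'
#' A sensor-frame stream is a data frame with one row per time-stamped sample
#' of the instrumented trike. Time must be strictly increasing and the crank
#' angle is wrapped onto `[0, 360)` (so a logged `360` becomes `0`, the
#' vertical-down position of the right crank arm).
#'
#' @param df data frame with at least the mandatory columns
#'   `t_ms, crank_angle_deg, torque_left_nm, torque_right_nm,
#'   thigh_left_deg, thigh_right_deg`; optionally `stim_on` and `wheel_rev`.
#' @return the validated data frame with class `"sensor_frames"`.
#' @export
sensor_frames <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.cols_required, names(df))
  if (length(missing_cols)) {
    oida_abort(paste0("missing mandatory column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "oida_format_error")
  }
  keep <- intersect(c(.cols_required, .cols_optional), names(df))
  df <- as.data.frame(df)[keep]
  for (ch in keep) {
    if (!is.numeric(df[[ch]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[ch]]))))
      oida_abort(sprintf("column '%s' is not numeric (e.g. data row %s)",
                         ch, paste(utils::head(bad, 5L), collapse = ", ")),
                 "oida_format_error")
    }
    bad <- which(!is.finite(df[[ch]]))
    if (length(bad)) {
      oida_abort(sprintf("column '%s' has missing/non-finite values at data row(s) %s",
                         ch, paste(utils::head(bad, 5L), collapse = ", ")),
                 "oida_format_error")
    }
  }
  t <- df$t_ms
  if (nrow(df) > 1L) {
    i <- which(diff(t) <= 0)
    if (length(i)) {
      oida_abort(sprintf(
        "time not strictly increasing at data row %d (t_ms = %g after %g)",
        i[1L] + 1L, t[i[1L] + 1L], t[i[1L]]), "oida_data_error")
    }
  }
  df$crank_angle_deg <- wrap_angle(df$crank_angle_deg, 360)
  rownames(df) <- NULL
  class(df) <- c("sensor_frames", "data.frame")
  df
}

#' Read a session log CSV
#'
#' Reads the documented CSV dialect (see [sensor_frames()] for the column
#' set) and validates the stream. Malformed rows are reported with their
#' data-row numbers; non-monotonic time is reported with the offending
#' timestamp.
#'
#' @param path path to a CSV session log.
#' @return a [sensor_frames()] data frame.
#' @seealso [write_log()]
#' @export
read_log <- function(path) {
  if (!file.exists(path)) {
    oida_abort(sprintf("log file not found: %s", path), "oida_format_error")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  sensor_frames(df)
}

#' Write a session log CSV
#'
#' Inverse of [read_log()]; values are written with full double precision
#' (up to 15 significant digits), so `read_log(write_log(x))` reproduces `x`.
#'
#' @param frames a [sensor_frames()] stream.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_log <- function(frames, path) {
  frames <- sensor_frames(frames)
  utils::write.csv(frames, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sensor and muscle latency model
#'
#' Transmission/processing latencies of the two sensor modalities and the
#' electromechanical delay of the stimulated muscle. Defaults are the
#' latencies of the reference hardware: 200 ms for the wireless crank
#' power-meter, 40 ms for the IMU's internal Kalman filter, and an
#' empirically estimated 200 ms muscular delay.
#'
#' @param sensor_crank_ms power-meter latency (crank angle and both torque
#'   channels share one packet, hence one latency) in ms.
#' @param sensor_imu_ms IMU (thigh angle / cycling phase) latency in ms.
#' @param muscle_ms muscle electromechanical delay in ms.
#' @return an object of class `"delay_model"`.
#' @export
delay_model <- function(sensor_crank_ms = 200, sensor_imu_ms = 40,
                        muscle_ms = 200) {
  vals <- c(sensor_crank_ms, sensor_imu_ms, muscle_ms)
  stopifnot(is.numeric(vals), length(vals) == 3L, all(is.finite(vals)))
  if (any(vals < 0)) oida_abort("delays must be >= 0", "oida_config_error")
  structure(list(sensor_crank_ms = sensor_crank_ms,
                 sensor_imu_ms = sensor_imu_ms,
                 muscle_ms = muscle_ms),
            class = "delay_model")
}

#' @export
print.delay_model <- function(x, ...) {
  cat(sprintf("<delay_model> crank sensor %g ms, IMU %g ms, muscle %g ms\n",
              x$sensor_crank_ms, x$sensor_imu_ms, x$muscle_ms))
  invisible(x)
}

#' Sensor delay for a given control-signal kind
#' @param delays a [delay_model()].
#' @param signal `"crank"` (power meter) or `"phase"` (IMU).
#' @return delay in ms.
#' @export
sensor_delay <- function(delays, signal = c("crank", "phase")) {
  signal <- match.arg(signal)
  stopifnot(inherits(delays, "delay_model"))
  switch(signal, crank = delays$sensor_crank_ms, phase = delays$sensor_imu_ms)
}

#' Measurement-session configuration
#'
#' Parameters of one interval-detection measurement: the target muscle
#' channel, the stimulation settings used during the active cycles, how many
#' accepted cycles to average per phase, and the cadence gate. Defaults are
#' the reference protocol: 400 us / 72 mA / 40 Hz continuous stimulation,
#' 3 cycles per phase at a target cadence of 5 RPM with 50 % tolerance.
#'
#' @param channel muscle channel id; `"LQ"`, `"RQ"`, `"LH"`, `"RH"`
#'   (left/right quadriceps/hamstrings) or a user-defined name (then pass
#'   `side` explicitly to [oida()]).
#' @param stim_frequency_hz,stim_amplitude_ma,stim_phasewidth_us stimulation
#'   parameters (recorded in the output pattern; not used in computation).
#' @param n_cycles number of accepted cycles averaged per phase (>= 1). Note
#'   the recording must contain `n_cycles + 1` accepted active cycles because
#'   the first accepted active cycle is rejected (onset transient).
#' @param target_cadence_rpm target cadence of the manual pedalling, RPM.
#' @param cadence_tolerance accepted relative deviation from the target,
#'   as a fraction in (0, 1).
#' @param signal_kind control signal: `"crank"` (crank angle, 0-360 deg) or
#'   `"phase"` (IMU cycling phase, 0-100 %).
#' @return an object of class `"session_config"`.
#' @export
session_config <- function(channel = "LQ", stim_frequency_hz = 40,
                           stim_amplitude_ma = 72, stim_phasewidth_us = 400,
                           n_cycles = 3, target_cadence_rpm = 5,
                           cadence_tolerance = 0.5,
                           signal_kind = c("crank", "phase")) {
  signal_kind <- match.arg(signal_kind)
  if (!is.numeric(n_cycles) || n_cycles < 1) {
    oida_abort("n_cycles must be >= 1", "oida_config_error")
  }
  if (!is.numeric(target_cadence_rpm) || target_cadence_rpm <= 0) {
    oida_abort("target_cadence_rpm must be > 0", "oida_config_error")
  }
  if (!is.numeric(cadence_tolerance) || cadence_tolerance <= 0 ||
      cadence_tolerance >= 1) {
    oida_abort("cadence_tolerance must be in (0, 1)", "oida_config_error")
  }
  structure(list(channel = channel,
                 stim_frequency_hz = stim_frequency_hz,
                 stim_amplitude_ma = stim_amplitude_ma,
                 stim_phasewidth_us = stim_phasewidth_us,
                 n_cycles = as.integer(n_cycles),
                 target_cadence_rpm = target_cadence_rpm,
                 cadence_tolerance = cadence_tolerance,
                 signal_kind = signal_kind),
            class = "session_config")
}

#' Read a session configuration from YAML or JSON
#'
#' Keys mirror the arguments of [session_config()]; absent keys keep their
#' defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [session_config()].
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) {
    oida_abort(sprintf("config file not found: %s", path), "oida_format_error")
  }
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(session_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) {
    oida_abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
               "oida_config_error")
  }
  do.call(session_config, lst)
}

#' Side of a muscle channel
#' @param channel channel id.
#' @return `"left"`, `"right"`, or `NA` for user-defined channels.
#' @export
muscle_side <- function(channel) {
  switch(toupper(substr(channel, 1L, 1L)), L = "left", R = "right",
         NA_character_)
}

#' Align sensor streams onto a common uniform clock
#'
#' Each logged sample reports the physical state as it was one sensor
#' latency earlier, so the power-meter channels (crank angle, both torques)
#' are shifted backwards in time by the crank-sensor delay and the IMU
#' channels (thigh angles) by the IMU delay; command channels (`stim_on`,
#' `wheel_rev`) carry no sensor latency and are not shifted. All channels are
#' then linearly interpolated onto one uniform grid (default 100 Hz, the
#' controller's processing rate). The crank angle is unwrapped before
#' interpolation and re-wrapped to `[0, 360)` afterwards, so interpolated
#' values never jump across the 360 -> 0 seam. No extrapolation is performed:
#' grid points not covered by every channel after shifting (the tail of the
#' session, up to the largest delay) are dropped.
#'
#' @param frames a [sensor_frames()] stream.
#' @param delays a [delay_model()] (or a bare list with the same fields;
#'   `delay_model()` enforces physical non-negativity, the alignment itself
#'   is defined for any shift).
#' @param grid_hz output grid rate in Hz (default 100).
#' @return a [sensor_frames()] stream on the uniform grid. `stim_on` is
#'   carried by zero-order hold; `wheel_rev` events are mapped to the nearest
#'   grid sample.
#' @export
align_streams <- function(frames, delays = delay_model(), grid_hz = 100) {
  frames <- sensor_frames(frames)
  stopifnot(is.numeric(grid_hz), grid_hz > 0)
  t <- frames$t_ms
  n <- nrow(frames)
  if (n < 2L) oida_abort("stream too short to align", "oida_alignment_error")
  step <- 1000 / grid_hz

  chans <- setdiff(names(frames), "t_ms")
  d_of <- function(ch) {
    if (ch %in% .cols_power) delays$sensor_crank_ms
    else if (ch %in% .cols_imu) delays$sensor_imu_ms
    else 0
  }
  d <- vapply(chans, d_of, numeric(1L))
  lo <- max(t[1L] - d)
  hi <- min(t[n] - d)
  if (hi <= lo) {
    oida_abort("stream shorter than the largest sensor delay; cannot align",
               "oida_alignment_error")
  }
  k0 <- ceiling(lo / step - 1e-9)
  k1 <- floor(hi / step + 1e-9)
  if (k1 < k0 + 1L) {
    oida_abort("stream shorter than the largest sensor delay; cannot align",
               "oida_alignment_error")
  }
  gt <- (k0:k1) * step

  out <- data.frame(t_ms = gt)
  for (ch in chans) {
    ts <- t - d[[ch]]
    if (ch == "crank_angle_deg") {
      u <- unwrap_angle(frames[[ch]], 360)
      out[[ch]] <- wrap_angle(stats::approx(ts, u, xout = gt, rule = 1)$y, 360)
    } else if (ch == "stim_on") {
      out[[ch]] <- round(stats::approx(ts, frames[[ch]], xout = gt,
                                       method = "constant", f = 0, rule = 2)$y)
    } else if (ch == "wheel_rev") {
      ev <- ts[frames[[ch]] >= 1]
      flag <- numeric(length(gt))
      if (length(ev)) {
        idx <- round((ev - gt[1L]) / step) + 1L
        idx <- idx[idx >= 1L & idx <= length(gt)]
        flag <- as.numeric(tabulate(idx, nbins = length(gt)))
      }
      out[[ch]] <- flag
    } else {
      out[[ch]] <- stats::approx(ts, frames[[ch]], xout = gt, rule = 1)$y
    }
  }
  sensor_frames(out)
}
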