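# Pedalling-cycle detection in either control signal, the IMU cycling phase,
# and the cadence gate.

new_cycle <- function(data, kind, side = NA_character_) {
  duration <- data$t_ms[nrow(data)] - data$t_ms[1L]
  structure(list(data = data,
                 start_t = data$t_ms[1L],
                 end_t = data$t_ms[nrow(data)],
                 duration_ms = duration,
                 cadence_rpm = 60000 / duration,
                 kind = kind,
                 side = side),
            class = "oida_cycle")
}

#' @export
print.oida_cycle <- function(x, ...) {
  cat(sprintf("<oida_cycle> %s%s, t = [%g, %g] ms, duration %g ms (%.2f RPM), %d samples\n",
              x$kind, if (!is.na(x$side)) paste0("/", x$side) else "",
              x$start_t, x$end_t, x$duration_ms, x$cadence_rpm, nrow(x$data)))
  invisible(x)
}

# Upward crossings of multiples of `period` on an unwrapped signal.
# Levels are consumed monotonically (after a boundary fires, the next
# expected level is one period higher), so brief backward jitter around a
# boundary can never produce more than one boundary per revolution.
# If the stream starts exactly on a level, that start counts as a boundary.
level_crossings <- function(t, u, period) {
  n <- length(u)
  res_t <- numeric(0)
  res_l <- numeric(0)
  tol <- 1e-6 * max(1, period)
  l0 <- period * round(u[1L] / period)
  if (abs(u[1L] - l0) < tol) {
    res_t <- t[1L]
    res_l <- l0
    lv <- l0 + period
  } else {
    lv <- period * floor(u[1L] / period) + period
  }
  j <- 1L
  while (j < n) {
    if (u[j] < lv && u[j + 1L] >= lv) {
      du <- u[j + 1L] - u[j]
      tt <- t[j] + (lv - u[j]) / du * (t[j + 1L] - t[j])
      res_t <- c(res_t, tt)
      res_l <- c(res_l, lv)
      lv <- lv + period
    }
    j <- j + 1L
  }
  data.frame(time = res_t, level = res_l)
}

# Slice frames into cycles between consecutive boundaries, adding exact
# interpolated boundary rows at position 0 and `period`.
build_cycles <- function(t, u, period, torque_left, torque_right, crossings,
                         kind, side = NA_character_) {
  k <- nrow(crossings)
  if (k < 2L) return(list())
  interp <- function(y, tt) stats::approx(t, y, xout = tt, rule = 2)$y
  lapply(seq_len(k - 1L), function(ci) {
    t0 <- crossings$time[ci]
    t1 <- crossings$time[ci + 1L]
    lv <- crossings$level[ci]
    sel <- which(t > t0 & t < t1)
    dat <- data.frame(
      t_ms = c(t0, t[sel], t1),
      pos = pmin(pmax(c(0, u[sel] - lv, period), 0), period),
      torque_left_nm = c(interp(torque_left, t0), torque_left[sel],
                         interp(torque_left, t1)),
      torque_right_nm = c(interp(torque_right, t0), torque_right[sel],
                          interp(torque_right, t1)))
    new_cycle(dat, kind, side)
  })
}

#' Detect pedalling cycles from the crank angle
#'
#' One cycle per upward crossing of the crank angle through 0 deg (the
#' right crank arm vertically down, the stated reference position). Boundary
#' times are linearly interpolated between the samples bracketing the
#' crossing, and each cycle carries exact boundary rows at position 0 and
#' 360 deg. The crank angle is unwrapped first and boundary levels are
#' consumed monotonically, so small backward jitter near a boundary cannot
#' split a revolution. Partial first/last revolutions are discarded.
#'
#' @param frames aligned [sensor_frames()].
#' @return list of cycle objects (possibly empty if the stream contains less
#'   than one full revolution); each has fields `data` (columns `t_ms`,
#'   `pos` in deg within the cycle, `torque_left_nm`, `torque_right_nm`),
#'   `start_t`, `end_t`, `duration_ms`, `cadence_rpm`, `kind = "crank"`.
#' @export
detect_crank_cycles <- function(frames) {
  frames <- sensor_frames(frames)
  t <- frames$t_ms
  u <- unwrap_angle(frames$crank_angle_deg, 360)
  cr <- level_crossings(t, u, 360)
  build_cycles(t, u, 360, frames$torque_left_nm, frames$torque_right_nm,
               cr, kind = "crank")
}

# Alternating local extrema with an escape threshold `h`: an extremum is
# recorded once the signal has moved h away from the running extremum.
# The extremum of the initial segment is recorded as well (it is the stream
# start when the stream begins mid-limb; see compute_cycling_phase).
find_alternating_extrema <- function(theta, h) {
  n <- length(theta)
  idx <- integer(0)
  type <- character(0)
  dir <- 0L
  min_v <- max_v <- theta[1L]
  min_i <- max_i <- 1L
  for (i in seq_len(n)[-1L]) {
    v <- theta[i]
    if (v > max_v) { max_v <- v; max_i <- i }
    if (v < min_v) { min_v <- v; min_i <- i }
    if (dir >= 0L && v < max_v - h) {
      idx <- c(idx, max_i); type <- c(type, "max")
      dir <- -1L
      min_v <- v; min_i <- i
    } else if (dir <= 0L && v > min_v + h) {
      idx <- c(idx, min_i); type <- c(type, "min")
      dir <- 1L
      max_v <- v; max_i <- i
    }
  }
  data.frame(idx = idx, type = type)
}

#' Cycling phase from the thigh angle
#'
#' Normalizes the thigh angle (one IMU per leg) into a relative position
#' within each flexion-extension-flexion cycle: knee extension maps to
#' 0-50 %, knee flexion to 50-100 %. Within the extension half-cycle
#' `phase = 50 (theta - theta_flex) / (theta_ext - theta_flex)` and within
#' the flexion half-cycle
#' `phase = 50 + 50 (theta_ext - theta) / (theta_ext - theta_flex)`, where
#' `theta_flex`, `theta_ext` are the extrema of the most recently completed
#' cycle (the first cycle uses its own extrema, emitted retrospectively;
#' after the last completed cycle the latest known extrema are kept).
#'
#' Whether extension corresponds to a decreasing or increasing raw thigh
#' angle depends on the IMU mounting; the default is decreasing. Samples
#' before the first flexion extremum cannot be assigned a phase and are
#' dropped. A flexion extremum coinciding with the stream start whose value
#' is far from the later flexion extrema is treated as a mid-limb stream
#' start (not a true extremum) and the leading partial cycle is dropped.
#'
#' @param x a [sensor_frames()] stream (uses `thigh_<side>_deg`) or a data
#'   frame with columns `t_ms` and `theta_deg`.
#' @param side `"left"` or `"right"` (only used with sensor frames).
#' @param extension direction of knee extension in the raw thigh angle.
#' @param min_range_deg minimum peak-to-peak thigh excursion accepted as
#'   motion; below it a degenerate-motion error is raised. Half this value
#'   is also the escape threshold of the extremum detector.
#' @return data frame with columns `t_ms` and `phase` (percent in
#'   `[0, 100)`); empty if no complete cycle exists.
#' @export
compute_cycling_phase <- function(x, side = c("left", "right"),
                                  extension = c("decreasing", "increasing"),
                                  min_range_deg = 10) {
  side <- match.arg(side)
  extension <- match.arg(extension)
  if (inherits(x, "sensor_frames") ||
      (is.data.frame(x) && !"theta_deg" %in% names(x))) {
    x <- sensor_frames(x)
    t <- x$t_ms
    theta <- x[[paste0("thigh_", side, "_deg")]]
  } else {
    stopifnot(is.data.frame(x), all(c("t_ms", "theta_deg") %in% names(x)))
    t <- x$t_ms
    theta <- x$theta_deg
  }
  if (diff(range(theta)) < min_range_deg) {
    oida_abort(sprintf(
      "degenerate motion: thigh excursion %.2f deg below minimum range %g deg",
      diff(range(theta)), min_range_deg), "oida_degenerate_motion_error")
  }
  ext <- find_alternating_extrema(theta, min_range_deg / 2)
  flex_type <- if (extension == "decreasing") "max" else "min"
  if (nrow(ext) && ext$type[1L] != flex_type) ext <- ext[-1L, , drop = FALSE]
  empty <- data.frame(t_ms = numeric(0), phase = numeric(0))
  if (nrow(ext) < 2L) return(empty)

  fl <- ext$idx[ext$type == flex_type]
  if (length(fl) >= 3L) {
    # stream-start artefact: "extremum" at the very first sample, far from
    # the genuine flexion extrema observed later
    later <- theta[fl[-1L]]
    if (fl[1L] == 1L &&
        abs(theta[fl[1L]] - stats::median(later)) >
          0.25 * diff(range(theta))) {
      fl <- fl[-1L]
      ext <- ext[ext$idx >= fl[1L], , drop = FALSE]
    }
  }
  if (length(fl) < 2L) return(empty)

  n <- length(theta)
  phase <- rep(NA_real_, n)
  eps <- 1e-9
  k <- length(fl)
  # append stream end as pseudo-boundary so the tail is emitted too
  ends <- c(fl[-1L], n + 1L)
  use_f <- use_e <- NA_real_
  for (j in seq_len(k)) {
    i0 <- fl[j]
    i1 <- ends[j] - 1L
    if (i1 < i0) next
    # extension extremum inside this cycle (first opposite-type extremum
    # recorded after the flexion boundary)
    e_rows <- ext$idx[ext$type != flex_type & ext$idx > i0 &
                        ext$idx <= min(i1 + 1L, n)]
    e_i <- if (length(e_rows)) e_rows[1L] else NA_integer_
    complete <- j < k
    if (complete) {
      if (is.na(e_i)) next
      f_j <- theta[i0]
      e_j <- theta[e_i]
      if (j == 1L) { use_f <- f_j; use_e <- e_j }
    }
    if (is.na(use_f)) next  # no completed cycle yet to normalize against
    rng <- use_e - use_f
    idx_ext <- if (!is.na(e_i)) i0:(e_i - 1L) else i0:i1
    idx_flex <- if (!is.na(e_i) && e_i <= i1) e_i:i1 else integer(0)
    p_ext <- 50 * (theta[idx_ext] - use_f) / rng
    phase[idx_ext] <- pmin(pmax(p_ext, 0), 50 - eps)
    if (length(idx_flex)) {
      p_flex <- 50 + 50 * (use_e - theta[idx_flex]) / rng
      phase[idx_flex] <- pmin(pmax(p_flex, 50), 100 - eps)
    }
    if (complete) { use_f <- theta[i0]; use_e <- theta[e_i] }
  }
  keep <- !is.na(phase)
  data.frame(t_ms = t[keep], phase = phase[keep])
}

#' Detect cycles from the cycling-phase stream
#'
#' One cycle per wrap of the phase through 100 -> 0 %, i.e. per full
#' flexion-extension-flexion excursion; boundary handling mirrors
#' [detect_crank_cycles()]. Partial first/last cycles are discarded.
#'
#' @param phase data frame from [compute_cycling_phase()].
#' @param frames optional aligned [sensor_frames()] supplying the torque
#'   channels (interpolated at the phase sample times); without it the
#'   cycles carry zero torque and are only useful for timing/cadence.
#' @param side which leg the phase belongs to (annotation only).
#' @return list of cycle objects with `kind = "phase"` and `pos` in percent.
#' @export
detect_phase_cycles <- function(phase, frames = NULL,
                                side = NA_character_) {
  stopifnot(is.data.frame(phase), all(c("t_ms", "phase") %in% names(phase)))
  if (nrow(phase) < 2L) return(list())
  t <- phase$t_ms
  u <- unwrap_angle(phase$phase, 100)
  cr <- level_crossings(t, u, 100)
  if (is.null(frames)) {
    tl <- tr <- numeric(length(t))
  } else {
    frames <- sensor_frames(frames)
    tl <- stats::approx(frames$t_ms, frames$torque_left_nm, xout = t,
                        rule = 2)$y
    tr <- stats::approx(frames$t_ms, frames$torque_right_nm, xout = t,
                        rule = 2)$y
  }
  build_cycles(t, u, 100, tl, tr, cr, kind = "phase", side = side)
}

#' Cadence gate for recorded cycles
#'
#' A cycle is accepted iff its cadence lies within
#' `target * (1 - tolerance)` and `target * (1 + tolerance)`, bounds
#' inclusive (rejection is strictly outside the band: at the default
#' 5 RPM +/- 50 % a cycle is rejected above 7.5 or below 2.5 RPM).
#'
#' @param cycle a cycle object or a numeric vector of cadences in RPM.
#' @param target_cadence_rpm target cadence, RPM (> 0).
#' @param tolerance relative tolerance, fraction in (0, 1).
#' @return logical: accepted?
#' @export
validate_cadence <- function(cycle, target_cadence_rpm, tolerance) {
  stopifnot(is.numeric(target_cadence_rpm), target_cadence_rpm > 0,
            is.numeric(tolerance), tolerance > 0, tolerance < 1)
  cad <- if (inherits(cycle, "oida_cycle")) cycle$cadence_rpm else cycle
  stopifnot(is.numeric(cad))
  cad >= target_cadence_rpm * (1 - tolerance) &
    cad <= target_cadence_rpm * (1 + tolerance)
}
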