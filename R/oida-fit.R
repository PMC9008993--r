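# The full detection pipeline and the fitted-object methods.

#' Detect the optimal stimulation interval from a recorded session
#'
#' Runs the complete pipeline on a raw sensor log containing a passive
#' (unstimulated) segment followed by an active (continuously stimulated)
#' segment: streams are delay-aligned onto the 100 Hz processing grid,
#' pedalling cycles are segmented from the configured control signal,
#' cycles outside the cadence gate are rejected, the first accepted active
#' cycle is rejected (onset transient at stimulation switch-on), the first
#' `n_cycles` accepted cycles of each segment are resampled onto the
#' position template and averaged, and the optimal stimulation interval is
#' the positive run of the net torque (active minus passive) around its
#' maximum.
#'
#' @param frames raw [sensor_frames()] (e.g. from [read_log()] or
#'   [simulate_session()]).
#' @param config a [session_config()].
#' @param delays a [delay_model()].
#' @param split_t_ms explicit passive/active split time in ms, used when
#'   the log carries no `stim_on` flags.
#' @param side torque channel / leg; inferred from the channel id for the
#'   standard `LQ`/`RQ`/`LH`/`RH` names.
#' @param smooth_window optional circular moving-average window (bins)
#'   applied to the net torque before the interval search; 0 (default)
#'   disables it.
#' @param grid_hz processing rate for alignment.
#' @return an object of class `"oida"`; see [print.oida()],
#'   [summary.oida()], [coef.oida()], [plot.oida()], [predict.oida()],
#'   [residuals.oida()]. Fields include `interval` (the detected
#'   [stim_interval()]), `profiles` (`$passive`, `$active`,
#'   `$net`), `cycles` (per-cycle diagnostics data frame) and
#'   `cycle_profiles` (the per-cycle template profiles that entered the
#'   averages).
#' @export
oida <- function(frames, config = session_config(), delays = delay_model(),
                 split_t_ms = NULL, side = NULL, smooth_window = 0,
                 grid_hz = 100) {
  stopifnot(inherits(config, "session_config"),
            inherits(delays, "delay_model"))
  side <- side %||% muscle_side(config$channel)
  if (is.na(side)) {
    oida_abort(sprintf(
      "cannot infer the leg for channel '%s'; pass side = \"left\"/\"right\"",
      config$channel), "oida_config_error")
  }
  al <- align_streams(frames, delays, grid_hz)

  if (config$signal_kind == "crank") {
    cycles <- detect_crank_cycles(al)
  } else {
    ph <- compute_cycling_phase(al, side = side)
    cycles <- detect_phase_cycles(ph, al, side = side)
  }
  if (!length(cycles)) {
    oida_abort("no complete cycle found in the recording",
               "oida_insufficient_cycles_error")
  }

  seg_of <- function(cy) {
    if ("stim_on" %in% names(al)) {
      s <- al$stim_on[al$t_ms >= cy$start_t & al$t_ms <= cy$end_t]
      if (all(s >= 1)) "active" else if (all(s < 1)) "passive" else "mixed"
    } else if (!is.null(split_t_ms)) {
      if (cy$end_t <= split_t_ms) "passive"
      else if (cy$start_t >= split_t_ms) "active" else "mixed"
    } else {
      oida_abort("log has no stim_on flags; supply split_t_ms",
                 "oida_config_error")
    }
  }
  segment <- vapply(cycles, seg_of, character(1L))
  accepted <- vapply(cycles, validate_cadence, logical(1L),
                     config$target_cadence_rpm, config$cadence_tolerance)

  diag <- data.frame(
    cycle = seq_along(cycles),
    start_t_ms = vapply(cycles, `[[`, numeric(1L), "start_t"),
    duration_ms = vapply(cycles, `[[`, numeric(1L), "duration_ms"),
    cadence_rpm = vapply(cycles, `[[`, numeric(1L), "cadence_rpm"),
    segment = segment,
    accepted = accepted,
    used = FALSE,
    note = "")

  idx_passive <- which(segment == "passive" & accepted)
  idx_active <- which(segment == "active" & accepted)
  if (length(idx_active)) {
    diag$note[idx_active[1L]] <- "first active cycle rejected (onset transient)"
    idx_active <- idx_active[-1L]
  }
  n <- config$n_cycles
  if (length(idx_passive) < n) {
    oida_abort(sprintf("insufficient cycles (passive: %d/%d)",
                       length(idx_passive), n),
               "oida_insufficient_cycles_error",
               segment = "passive", found = length(idx_passive), needed = n)
  }
  if (length(idx_active) < n) {
    oida_abort(sprintf("insufficient cycles (active: %d/%d)",
                       length(idx_active), n),
               "oida_insufficient_cycles_error",
               segment = "active", found = length(idx_active), needed = n)
  }
  idx_passive <- idx_passive[seq_len(n)]
  idx_active <- idx_active[seq_len(n)]
  diag$used[c(idx_passive, idx_active)] <- TRUE

  domain <- config$signal_kind
  prof_of <- function(i) normalize_cycle(cycles[[i]], domain = domain,
                                         side = side)
  p_passive <- lapply(idx_passive, prof_of)
  p_active <- lapply(idx_active, prof_of)
  passive_mean <- average_profiles(p_passive)
  active_mean <- average_profiles(p_active)
  net <- net_torque(active_mean, passive_mean)
  interval <- detect_optimal_interval(net, smooth_window = smooth_window)

  structure(list(interval = interval,
                 profiles = list(passive = passive_mean,
                                 active = active_mean, net = net),
                 cycles = diag,
                 cycle_profiles = list(passive = p_passive,
                                       active = p_active),
                 config = config, delays = delays, side = side,
                 call = match.call()),
            class = "oida")
}

#' @rdname oida
#' @param ... passed on to [oida()].
#' @export
run_oida <- function(frames, config = session_config(),
                     delays = delay_model(), ...) {
  oida(frames, config, delays, ...)
}

#' @export
print.oida <- function(x, ...) {
  unit <- if (x$interval$span == 360) "deg" else "%"
  cat("Optimal stimulation interval detection\n")
  cat(sprintf("  channel      %s (%s leg), control signal: %s\n",
              x$config$channel, x$side, x$config$signal_kind))
  cat(sprintf("  cycles used  %d passive + %d active (first active rejected)\n",
              x$config$n_cycles, x$config$n_cycles))
  cat(sprintf("  interval     %s\n", format(x$interval)))
  cat(sprintf("  peak net     %.2f N·m at %d %s\n",
              max(x$profiles$net$values),
              which.max(x$profiles$net$values) - 1L, unit))
  invisible(x)
}

#' Summary of a fitted detection
#' @param object an `"oida"` fit.
#' @param ... unused.
#' @export
summary.oida <- function(object, ...) {
  net <- object$profiles$net
  out <- list(fit = object,
              interval = object$interval,
              width = interval_width(object$interval),
              peak_net_nm = max(net$values),
              peak_at = which.max(net$values) - 1L,
              cycles = object$cycles)
  class(out) <- "summary.oida"
  out
}

#' @export
print.summary.oida <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  width        %.0f of %g\n", x$width, x$interval$span))
  cat("\nPer-cycle diagnostics:\n")
  print(x$cycles, row.names = FALSE)
  invisible(x)
}

#' Detected interval endpoints
#' @param object an `"oida"` fit.
#' @param ... unused.
#' @return named numeric `c(start, stop)` in domain units.
#' @export
coef.oida <- function(object, ...) {
  c(start = object$interval$start, stop = object$interval$stop)
}

#' Stimulation command for new positions
#'
#' Evaluates the fitted interval, optionally delay-compensated for a given
#' cadence, at new control-signal positions.
#'
#' @param object an `"oida"` fit.
#' @param positions numeric positions in the fit's domain units.
#' @param cadence_rpm cadence for the compensation (default: the target
#'   cadence of the fit's configuration).
#' @param delays a [delay_model()] (default: the fit's).
#' @param compensate apply delay compensation.
#' @param ... unused.
#' @return logical vector: stimulate at each position?
#' @export
predict.oida <- function(object, positions,
                         cadence_rpm = object$config$target_cadence_rpm,
                         delays = object$delays, compensate = TRUE, ...) {
  iv <- object$interval
  use <- if (compensate) {
    compensate_interval(iv, delays, 60000 / cadence_rpm,
                        signal = object$config$signal_kind)
  } else iv
  in_interval(positions, use)
}

#' Per-cycle deviations from the segment means
#'
#' @param object an `"oida"` fit.
#' @param ... unused.
#' @return numeric matrix, one row per used cycle
#'   (`passive1..n, active1..n`), one column per template bin: the cycle's
#'   template profile minus its segment's mean profile.
#' @export
residuals.oida <- function(object, ...) {
  rows <- c(lapply(object$cycle_profiles$passive, function(p)
    p$values - object$profiles$passive$values),
    lapply(object$cycle_profiles$active, function(p)
      p$values - object$profiles$active$values))
  m <- do.call(rbind, rows)
  rownames(m) <- c(paste0("passive", seq_along(object$cycle_profiles$passive)),
                   paste0("active", seq_along(object$cycle_profiles$active)))
  colnames(m) <- 0:object$profiles$net$span
  m
}

#' Plot the averaged torque profiles and the detected interval
#'
#' Passive mean (blue), active mean (red) and net torque (orange) over the
#' position template, with the detected stimulation interval shaded.
#'
#' @param x an `"oida"` fit.
#' @param ... further arguments passed to [graphics::matplot()].
#' @export
plot.oida <- function(x, ...) {
  bins <- profile_bins(x$profiles$net)
  span <- x$profiles$net$span
  unit <- if (span == 360) "crank angle [deg]" else "cycling phase [%]"
  m <- cbind(x$profiles$passive$values, x$profiles$active$values,
             x$profiles$net$values)
  graphics::matplot(bins, m, type = "l", lty = 1, lwd = 2,
                    col = c("steelblue", "firebrick", "darkorange"),
                    xlab = unit, ylab = "torque [N·m]", ...)
  usr <- graphics::par("usr")
  shade <- grDevices::adjustcolor("lightblue", 0.35)
  iv <- x$interval
  rects <- if (iv$full_cycle) list(c(0, span))
           else if (iv$start < iv$stop) list(c(iv$start, iv$stop))
           else list(c(iv$start, span), c(0, iv$stop))
  for (rg in rects) {
    graphics::rect(rg[1L], usr[3L], rg[2L], usr[4L], col = shade,
                   border = NA)
  }
  graphics::abline(h = 0, col = "grey60")
  graphics::legend("topright",
                   legend = c("passive", "active", "net"),
                   col = c("steelblue", "firebrick", "darkorange"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
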