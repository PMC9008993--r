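#' Circular stimulation interval
#'
#' A stimulation interval is the range of the control signal (crank angle in
#' degrees or cycling phase in percent) within which a muscle channel receives
#' stimulation. Intervals live on a circle: `start` may exceed `stop`, in
#' which case the interval wraps through 0 (e.g. a quadriceps interval
#' 259 -> 68 degrees covers the top-dead-centre). A degenerate interval that
#' covers the whole cycle is represented explicitly via `full_cycle`.
#'
#' @param start,stop interval endpoints in domain units, each in `[0, span)`.
#'   Membership is half-open: a position `p` is inside iff
#'   `start <= p < stop` (or the wrapped equivalent).
#' @param span domain span: 360 for the crank-angle domain, 100 for the
#'   cycling-phase domain.
#' @param full_cycle logical; if `TRUE` the interval covers the whole cycle
#'   and `start`/`stop` are ignored for membership.
#' @return an object of class `"stim_interval"`.
#' @examples
#' iv <- stim_interval(259, 68)        # wraps through 0 deg
#' in_interval(c(300, 0, 67, 68, 100), iv)
#' interval_width(iv)
#' @export
stim_interval <- function(start, stop, span = 360, full_cycle = FALSE) {
  stopifnot(is.numeric(start), is.numeric(stop), length(start) == 1L,
            length(stop) == 1L, is.numeric(span), span > 0)
  if (!is.finite(start) || !is.finite(stop)) {
    oida_abort("interval endpoints must be finite", "oida_interval_error")
  }
  if (start < 0 || start >= span || stop < 0 || stop >= span) {
    oida_abort(sprintf("interval endpoints must lie in [0, %g)", span),
               "oida_interval_error")
  }
  if (!full_cycle && start == stop) {
    oida_abort("start == stop is only valid for a full-cycle interval",
               "oida_interval_error")
  }
  structure(list(start = start, stop = stop, span = span,
                 full_cycle = isTRUE(full_cycle)),
            class = "stim_interval")
}

#' Width of a circular interval in domain units
#' @param interval a [stim_interval()].
#' @return numeric width in `[0, span]`; `span` for a full-cycle interval.
#' @export
interval_width <- function(interval) {
  stopifnot(inherits(interval, "stim_interval"))
  if (interval$full_cycle) return(interval$span)
  (interval$stop - interval$start) %% interval$span
}

#' Circular interval membership
#'
#' Half-open membership on the circle: for `start < stop` a position is
#' inside iff `start <= p < stop`; for a wrapping interval
#' (`start > stop`) iff `p >= start` or `p < stop`. Positions are wrapped
#' onto `[0, span)` first.
#'
#' @param position numeric vector of positions in domain units.
#' @param interval a [stim_interval()].
#' @return logical vector.
#' @export
in_interval <- function(position, interval) {
  stopifnot(inherits(interval, "stim_interval"), is.numeric(position))
  if (interval$full_cycle) return(rep(TRUE, length(position)))
  p <- wrap_angle(position, interval$span)
  s <- interval$start
  e <- interval$stop
  if (s < e) p >= s & p < e else p >= s | p < e
}

#' @export
format.stim_interval <- function(x, ...) {
  unit <- if (x$span == 360) "°" else if (x$span == 100) "%" else ""
  if (x$full_cycle) {
    sprintf("full cycle (span %g%s)", x$span, unit)
  } else {
    sprintf("%g%s → %g%s%s", x$start, unit, x$stop, unit,
            if (x$stop < x$start) " (wraps through 0)" else "")
  }
}

#' @export
print.stim_interval <- function(x, ...) {
  cat("<stim_interval> ", format(x), "\n", sep = "")
  invisible(x)
}
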