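# Builders and independent brute-force oracles used across the suite.

# constant-velocity crank stream (no sensor delays applied)
make_crank_frames <- function(duration_ms, cadence_rpm = 5, hz = 100,
                              torque_left = function(theta) 0 * theta,
                              torque_right = function(theta) 0 * theta,
                              start_deg = 0, stim_on = NULL) {
  t <- seq(0, duration_ms, by = 1000 / hz)
  rate <- cadence_rpm * 360 / 60000  # deg per ms
  u <- start_deg + rate * t
  df <- data.frame(
    t_ms = t,
    crank_angle_deg = u %% 360,
    torque_left_nm = torque_left(u %% 360),
    torque_right_nm = torque_right(u %% 360),
    thigh_left_deg = 20 + 25 * cos(u * pi / 180),
    thigh_right_deg = 20 + 25 * cos((u - 180) * pi / 180))
  if (!is.null(stim_on)) df$stim_on <- stim_on(t)
  sensor_frames(df)
}

# circular distance between two positions on a span
circ_err <- function(a, b, span = 360) {
  d <- (a - b) %% span
  pmin(d, span - d)
}

# Brute-force interval oracle: enumerate every maximal run of positive bins
# on the circle and pick the run containing the global maximum.
# Returns list(kind = "interval"/"full"/"none", start, stop).
oracle_interval <- function(values_full, span, zero_tol = 0) {
  v <- values_full[seq_len(span)]
  pos <- v > zero_tol
  if (!any(pos)) return(list(kind = "none"))
  if (all(pos)) return(list(kind = "full"))
  m <- which.max(v)
  runs <- list()
  b <- 1L
  while (b <= span) {
    if (pos[b]) {
      e <- b
      while (pos[((e) %% span) + 1L]) {
        e <- e + 1L
        if (e - b + 1L >= span) break
      }
      runs[[length(runs) + 1L]] <- c(b, ((e - 1L) %% span) + 1L)
      b <- e + 1L
    } else {
      b <- b + 1L
    }
  }
  # drop a leading run that is really the tail of a wrapped run
  if (length(runs) > 1L && runs[[1L]][1L] == 1L &&
      runs[[length(runs)]][2L] < runs[[length(runs)]][1L]) {
    runs <- runs[-1L]
  }
  inside <- function(run, i) {
    b <- run[1L]; e <- run[2L]
    if (b <= e) i >= b & i <= e else i >= b | i <= e
  }
  hit <- Filter(function(r) inside(r, m), runs)
  stopifnot(length(hit) == 1L)
  r <- hit[[1L]]
  list(kind = "interval", start = r[1L] - 1L, stop = r[2L] %% span)
}

# Exhaustive membership oracle over all integer positions of a span.
oracle_membership <- function(start, stop, span) {
  p <- 0:(span - 1L)
  if (start < stop) {
    p >= start & p < stop
  } else {
    p >= start | p < stop
  }
}

# Brute-force cycle-boundary oracle: scan all consecutive sample pairs for
# upward level crossings of the unwrapped signal, keeping only the first
# crossing of each successive level.
oracle_boundaries <- function(t, wrapped, period = 360) {
  u <- wrapped
  if (length(u) > 1L) {
    d <- diff(u)
    u <- u + c(0, cumsum(ifelse(d > period / 2, -period,
                                ifelse(d < -period / 2, period, 0))))
  }
  out <- numeric(0)
  lv <- period * (floor(u[1L] / period) + 1L)
  if (abs(u[1L] - period * round(u[1L] / period)) < 1e-6) {
    out <- t[1L]
    lv <- period * round(u[1L] / period) + period
  }
  for (i in seq_len(length(u) - 1L)) {
    if (u[i] < lv && u[i + 1L] >= lv) {
      out <- c(out, t[i])
      lv <- lv + period
    }
  }
  out
}
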