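# Template normalization, averaging, net torque and the interval search.

domain_span <- function(domain) switch(domain, crank = 360, phase = 100,
                                       oida_abort("unknown domain", "oida_domain_error"))

#' Torque profile on the fixed position template
#'
#' A torque profile holds torque values on the template vector of its
#' domain: crank angle 0-360 deg in 1 deg steps (361 bins) or cycling phase
#' 0-100 % in 1 % steps (101 bins). Bin 0 and the last bin are the same
#' physical position on the circle and always carry the same value.
#'
#' @param values numeric vector of length 361 (crank) or 101 (phase).
#' @param domain `"crank"` or `"phase"`.
#' @param n_cycles_averaged how many raw cycles the profile averages.
#' @return an object of class `"torque_profile"` with fields `domain`,
#'   `span`, `values`, `n_cycles_averaged`.
#' @export
torque_profile <- function(values, domain = c("crank", "phase"),
                           n_cycles_averaged = 1L) {
  domain <- match.arg(domain)
  span <- domain_span(domain)
  values <- as.numeric(values)
  if (length(values) != span + 1L) {
    oida_abort(sprintf("'%s' profile needs %d bins, got %d",
                       domain, span + 1L, length(values)),
               "oida_domain_error")
  }
  if (any(!is.finite(values))) {
    oida_abort("profile has missing bins", "oida_domain_error")
  }
  structure(list(domain = domain, span = span, values = values,
                 n_cycles_averaged = as.integer(n_cycles_averaged)),
            class = "torque_profile")
}

#' Template bin positions of a profile
#' @param profile a [torque_profile()].
#' @return integer positions `0:span`.
#' @export
profile_bins <- function(profile) 0:profile$span

#' @export
print.torque_profile <- function(x, ...) {
  unit <- if (x$domain == "crank") "deg" else "%"
  cat(sprintf("<%s> %s domain, %d bins of 1 %s, %d cycle(s) averaged, range [%.3f, %.3f] N·m\n",
              class(x)[1L], x$domain, x$span + 1L, unit, x$n_cycles_averaged,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Resample one cycle onto the position template
#'
#' Interpolates the cycle's torque linearly as a function of *position*
#' (crank angle or cycling phase), not time, at every template bin. This is
#' what makes the detection independent of the angular velocity during the
#' recording: two recordings of the same torque-versus-position function at
#' different (even varying) cadences produce the same profile up to
#' interpolation error.
#'
#' Bin 0 and the last bin are the same physical position; their interpolated
#' values are tied (averaged) so the profile is single-valued on the circle.
#'
#' @param cycle a cycle object from [detect_crank_cycles()] /
#'   [detect_phase_cycles()], or a data frame with columns `pos` and
#'   `torque` covering the domain once.
#' @param domain `"crank"` or `"phase"`; defaults to the cycle's own kind.
#' @param side which torque channel to use for a cycle object.
#' @param max_gap_bins largest tolerated gap in position coverage (in bins,
#'   i.e. domain units); a larger gap raises a sparse-cycle error.
#' @return a [torque_profile()] with `n_cycles_averaged = 1`.
#' @export
normalize_cycle <- function(cycle, domain = NULL,
                            side = c("left", "right"), max_gap_bins = 20) {
  side <- match.arg(side)
  if (inherits(cycle, "oida_cycle")) {
    domain <- domain %||% cycle$kind
    pos <- cycle$data$pos
    torque <- cycle$data[[paste0("torque_", side, "_nm")]]
  } else if (is.data.frame(cycle) && all(c("pos", "torque") %in% names(cycle))) {
    if (is.null(domain)) {
      oida_abort("domain must be given for a raw data frame", "oida_domain_error")
    }
    pos <- cycle$pos
    torque <- cycle$torque
  } else {
    oida_abort("cycle must be an oida_cycle or a data frame with pos/torque",
               "oida_domain_error")
  }
  domain <- match.arg(domain, c("crank", "phase"))
  span <- domain_span(domain)
  if (length(pos) < 2L) {
    oida_abort("cycle needs at least 2 samples", "oida_sparse_cycle_error")
  }
  ord <- order(pos)
  pos <- pos[ord]
  torque <- torque[ord]
  gaps <- diff(c(0, pos, span))
  if (max(gaps) > max_gap_bins) {
    oida_abort(sprintf(
      "sparse cycle: position coverage gap of %.1f bins exceeds maximum %g",
      max(gaps), max_gap_bins), "oida_sparse_cycle_error")
  }
  y <- stats::approx(pos, torque, xout = 0:span, ties = mean, rule = 2)$y
  edge <- mean(c(y[1L], y[span + 1L]))
  y[1L] <- y[span + 1L] <- edge
  torque_profile(y, domain, n_cycles_averaged = 1L)
}

#' Average torque profiles bin-wise
#'
#' @param profiles list of [torque_profile()]s on the same domain.
#' @return a [torque_profile()]; `n_cycles_averaged` sums the inputs.
#' @export
average_profiles <- function(profiles) {
  if (inherits(profiles, "torque_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1L), "torque_profile")))
  doms <- unique(vapply(profiles, `[[`, character(1L), "domain"))
  if (length(doms) != 1L) {
    oida_abort("cannot average profiles from different domains",
               "oida_domain_error")
  }
  m <- vapply(profiles, `[[`, numeric(profiles[[1L]]$span + 1L), "values")
  torque_profile(rowMeans(m), doms,
                 n_cycles_averaged = sum(vapply(profiles, `[[`, integer(1L),
                                                "n_cycles_averaged")))
}

#' Net torque: active minus passive
#'
#' The bin-wise difference between the mean active (stimulated) and mean
#' passive (unstimulated) torque profiles. Positive net torque marks
#' positions where the stimulated muscle contributes to the motion,
#' negative net torque where it resists.
#'
#' @param active,passive [torque_profile()]s on the same domain.
#' @return a profile of class `c("net_torque_profile", "torque_profile")`.
#' @export
net_torque <- function(active, passive) {
  stopifnot(inherits(active, "torque_profile"),
            inherits(passive, "torque_profile"))
  if (active$domain != passive$domain) {
    oida_abort("active and passive profiles are on different domains",
               "oida_domain_error")
  }
  out <- torque_profile(active$values - passive$values, active$domain,
                        n_cycles_averaged = active$n_cycles_averaged)
  class(out) <- c("net_torque_profile", class(out))
  out
}

# circular centred moving average over w bins (odd w)
circular_smooth <- function(v, w) {
  if (w <= 1L) return(v)
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(v)
  vv <- c(v[(n - half + 1L):n], v, v[1:half])
  as.numeric(stats::filter(vv, rep(1 / w, w), sides = 2))[(half + 1L):(half + n)]
}

#' Detect the optimal stimulation interval from the net torque
#'
#' Locates the template bin of maximal net torque (ties broken by the first
#' such bin scanning upward from bin 0), then walks circularly backwards to
#' the nearest non-positive-to-positive transition and forwards to the
#' nearest positive-to-non-positive transition. The reported `start` is the
#' first positive bin of that run and `stop` the first non-positive bin
#' after it, at integer bin resolution; every bin strictly inside
#' `(start, stop)` has positive net torque.
#'
#' @param net a net-torque [torque_profile()] on the full template.
#' @param smooth_window optional circular moving-average window (bins)
#'   applied before the search; `0` (default) disables smoothing.
#' @param zero_tol positivity threshold: a bin counts as positive only if
#'   its value exceeds `zero_tol`. The default, `1e-4` of the largest
#'   absolute bin value, absorbs the interpolation round-off that template
#'   resampling leaves where the true net torque is exactly zero, and is
#'   far below any physical torque scale. Set to `0` for a strict sign
#'   test.
#' @return a [stim_interval()]. If the net torque is positive at every bin a
#'   full-cycle interval is returned with `full_cycle = TRUE`; if the
#'   maximal net torque is not positive, a no-positive-contribution error is
#'   raised (the muscle never helps).
#' @export
detect_optimal_interval <- function(net, smooth_window = 0,
                                    zero_tol = NULL) {
  stopifnot(inherits(net, "torque_profile"))
  span <- net$span
  v <- net$values[seq_len(span)]  # bins 0..span-1; last bin repeats bin 0
  v <- circular_smooth(v, smooth_window)
  zero_tol <- zero_tol %||% (1e-4 * max(abs(v)))
  m <- which.max(v)
  if (v[m] <= zero_tol) {
    oida_abort("no positive net-torque contribution: the muscle never helps",
               "oida_no_positive_contribution_error")
  }
  if (all(v > zero_tol)) {
    return(stim_interval(0, 0, span, full_cycle = TRUE))
  }
  circ <- function(i) ((i - 1L) %% span) + 1L
  s <- m
  while (v[circ(s - 1L)] > zero_tol) s <- s - 1L
  e <- m
  while (v[circ(e + 1L)] > zero_tol) e <- e + 1L
  start_bin <- (s - 1L) %% span
  stop_bin <- e %% span
  stim_interval(start_bin, stop_bin, span)
}
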