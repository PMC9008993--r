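# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

oida_abort <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "oida_error")))
}

oida_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "oida_warning")))
}

#' Unwrap a circular signal given in degrees (or any period)
#'
#' Removes jumps larger than half a period so that the returned signal is
#' continuous. Assumes the true per-sample motion is below half a period,
#' which holds by a wide margin at pedalling cadences and 50-100 Hz sampling.
#'
#' @param x numeric vector of wrapped positions.
#' @param period domain span (360 for crank degrees, 100 for cycling phase).
#' @return numeric vector, continuous version of `x` (same first element).
#' @keywords internal
unwrap_angle <- function(x, period = 360) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  step <- ifelse(d > period / 2, -period, ifelse(d < -period / 2, period, 0))
  x + c(0, cumsum(step))
}

#' Wrap positions onto [0, period)
#' @keywords internal
wrap_angle <- function(x, period = 360) {
  y <- x %% period
  # guard against y == period from floating fuzz in %%
  y[y >= period] <- 0
  y
}

# "mm:ss" <-> seconds
parse_mmss <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) oida_abort("duration must be 'mm:ss'", "oida_format_error")
  as.numeric(parts[1L]) * 60 + as.numeric(parts[2L])
}

format_mmss <- function(seconds) {
  s <- round(seconds)
  sprintf("%02d:%02d", s %/% 60, s %% 60)
}

# evaluate RNG-dependent code under a local seed, restoring global RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
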