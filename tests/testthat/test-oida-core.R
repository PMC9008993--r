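# Template normalization, averaging, net torque, and the interval search.

test_that("cycles interpolate onto the template as a function of position", {
  cyc <- data.frame(pos = c(0, 90, 180, 270, 360),
                    torque = c(0, 1, 0, -1, 0))
  pr <- normalize_cycle(cyc, domain = "crank", max_gap_bins = 90)
  expect_length(pr$values, 361L)
  expect_equal(pr$values[45 + 1L], 0.5)        # linear midpoint
  expect_equal(pr$values[1L], pr$values[361L]) # circle is single-valued
  expect_equal(pr$n_cycles_averaged, 1L)

  const <- data.frame(pos = seq(0, 360, by = 5), torque = 2)
  expect_equal(normalize_cycle(const, domain = "crank")$values,
               rep(2, 361))
})

test_that("irregularly sampled torque is recovered within interpolation error", {
  withr::local_seed(11)
  # 77 irregular angles: jittered grid keeps coverage gaps well below the cap
  ang <- sort((0:76) * (360 / 76) + c(0, runif(75, -1.6, 1.6), 0))
  ang <- pmin(pmax(ang, 0), 360)
  cyc <- data.frame(pos = ang, torque = sin(ang * pi / 180))
  pr <- normalize_cycle(cyc, domain = "crank")
  expect_lt(max(abs(pr$values - sin(0:360 * pi / 180))), 0.01)
})

test_that("sparse position coverage is a detected error", {
  cyc <- data.frame(pos = c(0, 30, 60, 120, 330, 360),  # 210 deg hole
                    torque = 1)
  expect_error(normalize_cycle(cyc, domain = "crank", max_gap_bins = 20),
               class = "oida_sparse_cycle_error")
})

test_that("normalization is cadence-invariant", {
  tau <- function(theta) 2 * sin(theta * pi / 180) +
    0.5 * sin(2 * theta * pi / 180)
  prof <- function(cad) {
    fr <- make_crank_frames(2.2 * 60000 / cad, cadence_rpm = cad,
                            torque_left = tau)
    normalize_cycle(detect_crank_cycles(fr)[[1L]], side = "left")
  }
  p3 <- prof(3)
  p7 <- prof(7)
  expect_lt(max(abs(p3$values - p7$values)), 0.01)
  expect_lt(max(abs(p3$values - tau(0:360))), 0.01)
})

test_that("profiles average bin-wise and mixed domains are refused", {
  p1 <- torque_profile(rep(1, 361), "crank")
  p3 <- torque_profile(rep(3, 361), "crank")
  avg <- average_profiles(list(p1, p3))
  expect_equal(avg$values, rep(2, 361))
  expect_equal(avg$n_cycles_averaged, 2L)
  expect_equal(average_profiles(list(p1))$values, p1$values)
  q <- torque_profile(rep(1, 101), "phase")
  expect_error(average_profiles(list(p1, q)), class = "oida_domain_error")
})

test_that("averaging 3 cycles shrinks noise by sqrt(3)", {
  withr::local_seed(3)
  reps <- 150L
  pooled <- replicate(reps, {
    avg <- average_profiles(lapply(1:3, function(i)
      torque_profile(rnorm(361), "crank")))
    avg$values[seq_len(360)]
  })
  expect_equal(sd(as.numeric(pooled)), 1 / sqrt(3), tolerance = 0.05)
})

test_that("net torque is the exact bin-wise difference", {
  a <- torque_profile(c(sin(0:359 * pi / 180), 0), "crank")
  p <- torque_profile(rep(0.25, 361), "crank")
  nt <- net_torque(a, p)
  expect_s3_class(nt, "net_torque_profile")
  expect_identical(nt$values, a$values - p$values)
  self <- net_torque(a, a)
  expect_true(all(self$values == 0))
  # simulator ground truth: passive gravity + bump minus passive == bump
  bump <- active_contribution(0:360, stim_interval(30, 210), peak_nm = 5)
  grav <- -sin(0:360 * pi / 180)
  nt2 <- net_torque(torque_profile(grav + bump, "crank"),
                    torque_profile(grav, "crank"))
  expect_equal(nt2$values, bump, tolerance = 1e-12)
})

test_that("the interval search finds the positive run around the maximum", {
  v <- sin((0:360 - 30) * pi / 180)
  iv <- detect_optimal_interval(torque_profile(v, "crank"))
  expect_lte(circ_err(iv$start, 30), 1)
  expect_lte(circ_err(iv$stop, 210), 1)
  expect_false(iv$full_cycle)
  # all bins strictly inside are positive
  inside <- which(in_interval(0:359, iv)) - 1L
  inside <- setdiff(inside, iv$start)
  expect_true(all(v[inside + 1L] > 0))

  expect_error(
    detect_optimal_interval(torque_profile(rep(-0.5, 361), "crank")),
    class = "oida_no_positive_contribution_error")
  full <- detect_optimal_interval(torque_profile(rep(0.5, 361), "crank"))
  expect_true(full$full_cycle)
})

test_that("equal maxima break ties toward the first bin from 0", {
  v <- numeric(361)
  v[51:61] <- 1     # bins 50..60
  v[201:211] <- 1   # bins 200..210, same height
  iv <- detect_optimal_interval(torque_profile(v, "crank"), zero_tol = 0)
  expect_equal(iv$start, 50)
  expect_equal(iv$stop, 61)
})

test_that("interval search matches the brute-force positive-run oracle", {
  withr::local_seed(101)
  n_mismatch <- 0L
  for (i in 1:300) {
    span <- if (i %% 2L) 360L else 100L
    base <- rnorm(span, mean = runif(1, -1, 1))
    v <- c(base, base[1L])
    res <- tryCatch(
      detect_optimal_interval(torque_profile(
        v, if (span == 360L) "crank" else "phase"), zero_tol = 0),
      oida_no_positive_contribution_error = function(e) "none")
    orc <- oracle_interval(v, span, zero_tol = 0)
    ok <- if (identical(res, "none")) {
      orc$kind == "none"
    } else if (res$full_cycle) {
      orc$kind == "full"
    } else {
      orc$kind == "interval" && res$start == orc$start &&
        res$stop == orc$stop
    }
    if (!ok) n_mismatch <- n_mismatch + 1L
  }
  expect_equal(n_mismatch, 0L)
})

test_that("a simulated session is recovered end to end", {
  # ground truth chosen to exercise the wrap through 0 deg
  s <- simulate_session(simulation_config(true_interval = stim_interval(259, 68),
                                          seed = 7))
  fit <- oida(s, session_config(), delay_model())
  expect_s3_class(fit, "oida")
  expect_lte(circ_err(coef(fit)["start"], 259), 1)
  expect_lte(circ_err(coef(fit)["stop"], 68), 1)
  expect_equal(fit$profiles$passive$n_cycles_averaged, 3L)
  expect_equal(fit$profiles$active$n_cycles_averaged, 3L)
  # the methods are consistent with the fit
  expect_equal(unname(coef(fit)),
               c(fit$interval$start, fit$interval$stop))
  expect_true(all(predict(fit, c(300, 0, 60), compensate = FALSE)))
  expect_false(predict(fit, 150, compensate = FALSE))
  r <- residuals(fit)
  expect_equal(dim(r), c(6L, 361L))
  expect_equal(colMeans(r[1:3, ]), numeric(361),
               ignore_attr = TRUE, tolerance = 1e-12)
  s2 <- summary(fit)
  expect_s3_class(s2, "summary.oida")
  expect_output(print(s2), "Per-cycle diagnostics")
})

test_that("phase-domain sessions are recovered end to end", {
  s <- simulate_session(simulation_config(
    true_interval = stim_interval(97, 41, span = 100), domain = "phase",
    n_passive = 4, n_active = 6, tail_ms = 2000, seed = 5))
  fit <- oida(s, session_config(signal_kind = "phase"), delay_model())
  expect_lte(circ_err(coef(fit)["start"], 97, span = 100), 1)
  expect_lte(circ_err(coef(fit)["stop"], 41, span = 100), 1)
})

test_that("too few accepted cycles fail with a named segment and count", {
  s <- simulate_session(simulation_config(n_passive = 2, seed = 4))
  err <- expect_error(oida(s, session_config(), delay_model()),
                      class = "oida_insufficient_cycles_error")
  expect_match(conditionMessage(err), "passive: 2/3")
  s2 <- simulate_session(simulation_config(n_active = 3, seed = 4))
  err2 <- expect_error(oida(s2, session_config(), delay_model()),
                       class = "oida_insufficient_cycles_error")
  expect_match(conditionMessage(err2), "active: 2/3")
})

test_that("the first active cycle is excluded from the average", {
  cfg <- simulation_config(n_active = 5, seed = 12)
  s <- simulate_session(cfg)
  t_on <- attr(s, "truth")$t_on_ms
  clean <- oida(s, session_config(), delay_model())
  # inject a large transient strictly inside the first active revolution
  spiked <- s
  hit <- spiked$t_ms > t_on + 1500 & spiked$t_ms < t_on + 3000
  spiked$torque_left_nm[hit] <- spiked$torque_left_nm[hit] + 40
  fit <- oida(spiked, session_config(), delay_model())
  expect_equal(fit$profiles$active$values, clean$profiles$active$values,
               tolerance = 1e-10)
  expect_equal(coef(fit), coef(clean))
  expect_match(fit$cycles$note[fit$cycles$segment == "active" &
                                 fit$cycles$note != ""][1L],
               "first active cycle rejected")
})
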