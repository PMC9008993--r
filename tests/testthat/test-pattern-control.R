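# Delay compensation, circular membership, stimulation commands,
# session summaries.

test_that("start/stop shifts follow the closed forms", {
  d <- delay_model(200, 40, 200)
  # 60 RPM -> 1000 ms cycles
  expect_equal(shift_start(d, 1000, 360, "crank"), 144)
  expect_equal(shift_stop(40, 1000, 100), 4)
  expect_equal(shift_stop(200, 1200, 360), 60)   # 50 RPM
  z <- delay_model(0, 0, 0)
  expect_equal(shift_start(z, 1000, 360), 0)
  expect_equal(shift_stop(0, 777, 100), 0)
  # inverse proportionality to cycle duration
  expect_equal(shift_start(d, 2000, 360), shift_start(d, 1000, 360) / 2)
  expect_error(shift_start(d, 0, 360), class = "oida_domain_error")
})

test_that("closed forms hold for random positive inputs", {
  withr::local_seed(21)
  for (i in 1:200) {
    dm <- runif(1, 0, 400)
    ds <- runif(1, 0, 300)
    di <- runif(1, 0, 300)
    dur <- runif(1, 200, 30000)
    span <- sample(c(360, 100), 1L)
    d <- delay_model(ds, di, dm)
    sig <- sample(c("crank", "phase"), 1L)
    sd_used <- if (sig == "crank") ds else di
    expect_equal(shift_start(d, dur, span, sig),
                 (dm + sd_used) / dur * span, tolerance = 1e-12)
    expect_equal(shift_stop(d, dur, span, sig), sd_used / dur * span,
                 tolerance = 1e-12)
    # starting earlier at least as much as stopping earlier
    expect_gte(shift_start(d, dur, span, sig), shift_stop(d, dur, span, sig))
  }
})

test_that("interval compensation shifts both endpoints earlier", {
  iv <- stim_interval(259, 68)
  cmp <- compensate_interval(iv, delay_model(200, 40, 200), 1000, "crank")
  expect_equal(cmp$shift_start, 144)
  expect_equal(cmp$shift_stop, 72)
  expect_equal(cmp$start, 115)              # 259 - 144
  expect_equal(cmp$stop, 356)               # (68 - 72) mod 360
  expect_equal(interval_width(cmp), interval_width(iv) + 144 - 72)

  idle <- compensate_interval(iv, delay_model(0, 0, 0), 1000)
  expect_equal(idle$start, iv$start)
  expect_equal(idle$stop, iv$stop)

  wide <- stim_interval(5, 355)  # width 350
  expect_warning(
    res <- compensate_interval(wide, delay_model(200, 40, 200), 1000),
    class = "oida_saturation_warning")
  expect_true(res$full_cycle)
})

test_that("compensation commutes with the domain choice for proportional positions", {
  d <- delay_model(120, 120, 200)  # equal sensor delays isolate the scaling
  iv_deg <- stim_interval(200, 40, span = 360)
  iv_pct <- stim_interval(200 / 3.6, 40 / 3.6, span = 100)
  for (dur in c(1500, 4000, 12000)) {
    c_deg <- compensate_interval(iv_deg, d, dur, "crank")
    c_pct <- compensate_interval(iv_pct, d, dur, "phase")
    expect_equal(c_deg$start / 3.6, c_pct$start, tolerance = 1e-9)
    expect_equal(c_deg$stop / 3.6, c_pct$stop, tolerance = 1e-9)
  }
})

test_that("circular membership handles wrap-around and matches enumeration", {
  iv <- stim_interval(259, 68)
  expect_true(in_interval(300, iv))
  expect_false(in_interval(100, iv))
  ph <- stim_interval(99, 45, span = 100)
  expect_true(in_interval(10, ph))
  expect_true(all(in_interval(0:359, stim_interval(0, 0, full_cycle = TRUE))))

  withr::local_seed(33)
  for (i in 1:300) {
    span <- sample(c(360L, 100L), 1L)
    ab <- sample(0:(span - 1L), 2L)
    iv <- stim_interval(ab[1L], ab[2L], span)
    expect_identical(in_interval(0:(span - 1L), iv),
                     oracle_membership(ab[1L], ab[2L], span))
  }
})

test_that("commands switch ON earlier by exactly the start shift", {
  pat <- stim_pattern(LQ = stim_interval(259, 68))
  d <- delay_model(200, 40, 200)
  pos <- seq(0, 359.95, by = 0.05)
  raw <- stimulation_command(list(crank = pos), pat, d, 60,
                             compensate = FALSE)[, "LQ"]
  cmp <- stimulation_command(list(crank = pos), pat, d, 60)[, "LQ"]
  edge <- function(on) pos[which(diff(c(on[length(on)], on)) == 1L)]
  expect_equal((edge(raw) - edge(cmp)) %% 360, shift_start(d, 1000, 360),
               tolerance = 0.05 + 1e-9)
  # zero delays: command equals raw membership
  expect_identical(
    stimulation_command(list(crank = pos), pat, delay_model(0, 0, 0), 60),
    stimulation_command(list(crank = pos), pat, d, 60, compensate = FALSE))
  # halving the cadence doubles the shift in degrees
  c30 <- compensate_interval(pat$LQ$interval, d, 2000)
  c60 <- compensate_interval(pat$LQ$interval, d, 1000)
  expect_equal(c60$shift_start, 2 * c30$shift_start)
  expect_error(stimulation_command(list(), pat, d, 60),
               class = "oida_config_error")
})

test_that("ON time per cycle equals compensated width over span on replays", {
  fr <- make_crank_frames(3 * 2000 + 500, cadence_rpm = 30, hz = 100)
  pat <- stim_pattern(RQ = stim_interval(100, 250))
  d <- delay_model(100, 40, 150)
  rep <- replay_session(fr, pat, d, expected_cadence_rpm = 30)
  cmp <- compensate_interval(pat$RQ$interval, d, 2000)
  cyc <- detect_crank_cycles(align_streams(fr, d))
  for (cy in cyc) {
    rows <- rep$t_ms >= cy$start_t & rep$t_ms < cy$end_t
    frac <- mean(rep$cmd_RQ[rows])
    expect_equal(frac, interval_width(cmp) / 360,
                 tolerance = 2 / sum(rows))
  }
})

test_that("patterns round-trip through JSON", {
  pat <- stim_pattern(LQ = stim_interval(259, 68),
                      RH = stim_interval(14, 49, span = 100))
  path <- withr::local_tempfile(fileext = ".json")
  write_pattern(pat, path, n_cycles = 3L)
  back <- read_pattern(path)
  expect_equal(back$LQ$interval$start, 259)
  expect_equal(back$LQ$interval$stop, 68)
  expect_equal(back$RH$interval$span, 100)
  expect_equal(back$RH$side, "right")
})

test_that("session summaries report distance, speed, cadence and power", {
  # over-ground trial shape: 96 wheel revolutions of 2.1 m in 03:58 min
  t <- seq(0, 238000, by = 100)
  ev <- round(seq_len(96) * (238000 / 96) / 100) * 100
  df <- data.frame(t_ms = t, crank_angle_deg = (0.12 * t) %% 360,
                   torque_left_nm = 2, torque_right_nm = 1,
                   thigh_left_deg = 0, thigh_right_deg = 0,
                   wheel_rev = as.integer(t %in% ev))
  sm <- summarize_session(sensor_frames(df), wheel_circumference_m = 2.1)
  expect_equal(sm$duration, "03:58")
  expect_equal(sm$distance_m, 201.6)
  expect_equal(round(sm$speed_avg_kmh, 2), 3.05)
  expect_lte(sm$speed_avg_kmh, sm$speed_max_kmh)
  expect_lte(sm$cadence_avg_rpm, sm$cadence_max_rpm)
  # constant angular velocity and torque: power = total torque x omega
  expect_equal(sm$power_avg_w, 3 * 0.12 * 1000 * pi / 180, tolerance = 1e-6)

  # constant 10 km/h: 2.5 m circumference, one event every 0.9 s
  t2 <- seq(0, 90000, by = 10)
  df2 <- data.frame(t_ms = t2, crank_angle_deg = (0.18 * t2) %% 360,
                    torque_left_nm = 0, torque_right_nm = 0,
                    thigh_left_deg = 0, thigh_right_deg = 0,
                    wheel_rev = as.integer(t2 %% 900 == 0 & t2 > 0))
  sm2 <- summarize_session(sensor_frames(df2), 2.5)
  expect_equal(sm2$speed_avg_kmh, 10)
  expect_equal(sm2$speed_max_kmh, 10)

  # stationary: distance 0 and speed 0, cadence/power unavailable
  df3 <- df2
  df3$wheel_rev <- 0L
  df3$crank_angle_deg <- 42
  sm3 <- summarize_session(sensor_frames(df3), 2.5)
  expect_equal(sm3$distance_m, 0)
  expect_equal(sm3$speed_avg_kmh, 0)
  expect_true(is.na(sm3$cadence_avg_rpm))

  # no distance source: unavailable, not zero
  sm4 <- summarize_session(sensor_frames(df3[, !(names(df3) == "wheel_rev")]))
  expect_true(is.na(sm4$distance_m))
  expect_true(is.na(sm4$speed_avg_kmh))
})
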