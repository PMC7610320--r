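test_that("envelope filtering attenuates out-of-band content as the squared Butterworth predicts", {
  fs <- 2000
  time <- seq(0, 10, by = 1 / fs)
  # 5 Hz is a decade below the 50 Hz high-pass corner: the order-4
  # Butterworth magnitude there is 1e-4, squared by zero-phase filtering,
  # so essentially nothing survives rectification
  ch <- matrix(rep(sin(2 * pi * 5 * time), 12), ncol = 12,
               dimnames = list(NULL, SYNERGAIT_MUSCLES))
  env <- filter_emg(raw_emg(time, ch))
  expect_lt(max(as.matrix(env$channels)), 0.05)
  expect_true(all(as.matrix(env$channels) >= 0))

  # a 100 Hz carrier passes the high-pass; rectification leaves a DC level
  # of 2/pi * amplitude which the 20 Hz low-pass passes through
  ch2 <- matrix(rep(sin(2 * pi * 100 * time), 12), ncol = 12,
                dimnames = list(NULL, SYNERGAIT_MUSCLES))
  env2 <- filter_emg(raw_emg(time, ch2))
  interior <- env2$channels$MA[time > 2 & time < 8]
  expect_equal(mean(interior), 2 / pi, tolerance = 0.02)

  # all-zero input stays all-zero; the chain is amplitude-linear before
  # the rectifier, so scaling the input scales the envelope
  ch0 <- matrix(0, length(time), 12, dimnames = list(NULL, SYNERGAIT_MUSCLES))
  expect_true(all(as.matrix(filter_emg(raw_emg(time, ch0))$channels) == 0))
  env_a <- filter_emg(raw_emg(time, 3 * ch2))
  expect_equal(as.matrix(env_a$channels), 3 * as.matrix(env2$channels),
               tolerance = 1e-9)
})

test_that("filtering rejects too-low sampling rates and warns on short trials", {
  time <- seq(0, 1, by = 1 / 80)
  ch <- matrix(rnorm(length(time) * 12), ncol = 12,
               dimnames = list(NULL, SYNERGAIT_MUSCLES))
  expect_error(filter_emg(raw_emg(time, ch)), "too low")
  t2 <- seq(0, 0.2, by = 1 / 2000)
  ch2 <- matrix(rnorm(length(t2) * 12), ncol = 12,
                dimnames = list(NULL, SYNERGAIT_MUSCLES))
  expect_warning(filter_emg(raw_emg(t2, ch2)), "settling")
})

test_that("amplitude normalization maps channels to [0,1], flags degenerates, and is idempotent", {
  ch <- matrix(rep(c(2, 4, 6), 12), ncol = 12,
               dimnames = list(NULL, SYNERGAIT_MUSCLES))
  ch[, "SO"] <- 1   # constant channel
  env <- toy_envelope(ch)
  expect_warning(norm <- normalize_amplitude(env), "SO")
  expect_equal(norm$channels$MA, c(0, 0.5, 1))
  expect_equal(norm$channels$SO, c(0, 0, 0))
  expect_true(attr(norm, "degenerate")[["SO"]])
  expect_false(any(attr(norm, "degenerate")[setdiff(SYNERGAIT_MUSCLES, "SO")]))
  norm2 <- suppressWarnings(normalize_amplitude(norm))
  expect_equal(as.matrix(norm2$channels), as.matrix(norm$channels))
})

test_that("time normalization resamples stance and swing to 100 points each", {
  fs <- 2000
  time <- seq(0, 3.2, by = 1 / fs)
  # ramp channel: linear interpolation of a line preserves linearity
  ch <- matrix(rep(time, 12), ncol = 12,
               dimnames = list(NULL, SYNERGAIT_MUSCLES))
  env <- toy_envelope(ch, fs)
  env$time <- time
  ev <- gait_events(c(0, 1, 2, 3), rep(0.5, 4))
  nv <- time_normalize(env, ev, n_cycles = 3)
  expect_equal(dim(nv$V), c(12L, 600L))
  expect_equal(nv$n_cycles, 3L)
  # first cycle's stance: a linear ramp over [0, 0.5] at 100 points
  expect_equal(nv$V[1, 1:100], seq(0, 0.5, length.out = 100),
               tolerance = 1e-6)
  # endpoints of each phase are preserved
  expect_equal(unname(nv$V[1, 100]), 0.5, tolerance = 1e-6)
  expect_equal(unname(nv$V[1, 200]), 1.0, tolerance = 1e-6)
  # constant envelope stays constant
  env_c <- toy_envelope(matrix(0.7, length(time), 12,
                               dimnames = list(NULL, SYNERGAIT_MUSCLES)), fs)
  env_c$time <- time
  expect_true(all(abs(time_normalize(env_c, ev, n_cycles = 3)$V - 0.7) < 1e-12))
})

test_that("cycles that do not fit the recording are dropped with a warning", {
  fs <- 2000
  time <- seq(0, 2.5, by = 1 / fs)   # only 2 complete 1 s cycles fit
  env <- toy_envelope(matrix(runif(length(time) * 12), ncol = 12,
                             dimnames = list(NULL, SYNERGAIT_MUSCLES)), fs)
  env$time <- time
  ev <- gait_events(0:3, rep(0.6, 4))
  expect_warning(nv <- time_normalize(env, ev, n_cycles = 3), "2 of 3")
  expect_equal(ncol(nv$V), 400L)
})

test_that("threshold gait-event detection finds plateaus and ignores spikes", {
  fs <- 1000
  time <- seq(0, 5, by = 1 / fs)
  fz <- numeric(length(time))
  for (td in c(0.2, 1.2, 2.2, 3.2))
    fz[(round(td * fs) + 1):(round((td + 0.6) * fs) + 1)] <- 800
  ev <- detect_gait_events(force_recording(time, fz), 30, 0.05)
  expect_equal(ev$touchdowns, c(0.2, 1.2, 2.2, 3.2))
  expect_equal(ev$stance_durations, rep(0.6, 4))
  # 10 ms spike is shorter than min_contact and must be ignored
  fz2 <- fz; fz2[time >= 4.0 & time <= 4.01] <- 500
  ev2 <- detect_gait_events(force_recording(time, fz2), 30, 0.05)
  expect_equal(length(ev2$touchdowns), 4L)
  expect_warning(detect_gait_events(force_recording(time, 0 * fz)),
                 "no super-threshold")
})

test_that("gait parameters follow the two-steps-per-cycle convention", {
  ev <- gait_events(c(0, 1, 2, 3), rep(0.6, 4))
  gp <- compute_gait_parameters(ev)
  expect_equal(gp$cadence, 120)
  expect_equal(gp$stance_time, 0.6)
  expect_equal(gp$swing_time, 0.4)
  # 0.48 s cycles put cadence in the sprinting regime
  ev2 <- gait_events(seq(0, 2.4, by = 0.48), rep(0.15, 6))
  expect_equal(compute_gait_parameters(ev2)$cadence, 250)
  expect_error(compute_gait_parameters(gait_events(1, 0.6)), "two touchdowns")
  expect_error(gait_events(c(0, 1), c(1.5, 0.5)))
})

test_that("strike index separates rearfoot from mid/forefoot patterns", {
  si <- compute_strike_index(0, 0.05, 0.25)
  expect_equal(si$strike_index, 0.2)
  expect_equal(si$strike_pattern, "rearfoot")
  expect_equal(compute_strike_index(0, 0, 0.25)$strike_index, 0)
  si2 <- compute_strike_index(0.1, 0.1 + 0.74 * 0.25, 0.25)
  expect_equal(si2$strike_index, 0.74)
  expect_equal(si2$strike_pattern, "mid_forefoot")
  expect_warning(compute_strike_index(0, 0.3, 0.25), "clipping")
  expect_error(compute_strike_index(0, 0.1, -1), "positive")
})
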