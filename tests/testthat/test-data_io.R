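test_that("raw EMG round-trips through CSV with canonical channel order", {
  set.seed(11)
  time <- seq(0, 0.01, by = 5e-4)
  ch <- matrix(rnorm(length(time) * 12), ncol = 12)
  colnames(ch) <- rev(SYNERGAIT_MUSCLES)   # scrambled column order
  emg <- raw_emg(time, ch)
  expect_identical(names(emg$channels), SYNERGAIT_MUSCLES)

  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_emg(emg, path)
  back <- read_raw_emg(path)
  expect_identical(names(back$channels), SYNERGAIT_MUSCLES)
  expect_lt(max(abs(as.matrix(back$channels) - as.matrix(emg$channels))), 1e-12)
  expect_equal(back$time, emg$time, tolerance = 1e-12)
})

test_that("raw EMG validation names offending columns and rejects bad sampling", {
  time <- seq(0, 0.01, by = 5e-4)
  ch <- matrix(0, length(time), 12, dimnames = list(NULL, SYNERGAIT_MUSCLES))
  missing_so <- as.data.frame(ch)[setdiff(SYNERGAIT_MUSCLES, "SO")]
  expect_error(raw_emg(time, missing_so), "SO")
  extra <- cbind(as.data.frame(ch), XX = 0)
  expect_error(raw_emg(time, extra), "XX")
  t_bad <- time; t_bad[5] <- t_bad[5] + 1e-4
  expect_error(raw_emg(t_bad, ch), "ppm|increasing")
  # a 3-row 13-column toy file parses to 3 samples x 12 channels
  df <- data.frame(time = c(0, 5e-4, 1e-3), as.data.frame(ch[1:3, ]))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  toy <- read_raw_emg(path)
  expect_equal(length(toy$time), 3L)
  expect_equal(ncol(toy$channels), 12L)
})

test_that("cycle times validate stance-inside-cycle and round-trip", {
  ev <- gait_events(c(0, 1, 2), c(0.6, 0.6, 0.6))
  expect_length(ev$touchdowns, 3L)
  expect_error(gait_events(c(0, 1, 2), c(1.2, 0.6, 0.6)), "cycle 0")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cycle_times(ev, path)
  back <- read_cycle_times(path)
  expect_equal(back$touchdowns, ev$touchdowns)
  expect_equal(back$stance_durations, ev$stance_durations)
})

test_that("trial metadata round-trips through its JSON sidecar", {
  meta <- trial_meta("P07", group = "G2", locomotion = "R", speed = 8.3,
                     age = 21, mass = 65)
  expect_equal(meta$plate_sampling_rate, 1000)  # G2 force plate default
  path <- withr::local_tempfile(fileext = ".json")
  write_trial_meta(meta, path)
  back <- read_trial_meta(path)
  expect_equal(back$participant_code, "P07")
  expect_equal(back$speed, 8.3)
  expect_equal(back$group, "G2")
  expect_equal(back$age, 21)
  expect_error(trial_meta("P01", "G1", "W", speed = -1), "positive")
  expect_error(trial_meta("P01", "G1", "W", speed = 1,
                          emg_sampling_rate = 900), "1000 Hz")
})

test_that("decompositions persist as modules/primitives tables and reload", {
  W <- matrix(runif(24), 12, 2, dimnames = list(SYNERGAIT_MUSCLES, NULL))
  H <- matrix(runif(2 * 400), 2, 400)
  dec <- synergait:::new_decomposition(W, H, R2 = 0.93, iterations = 123,
                                       seed = 5L)
  dir <- withr::local_tempdir()
  paths <- write_decomposition(dec, dir, prefix = "TOY")
  w <- read.csv(file.path(dir, "TOY_modules.csv"))
  h <- read.csv(file.path(dir, "TOY_primitives.csv"))
  expect_equal(dim(w), c(12L, 3L))   # muscle column + 2 synergies
  expect_equal(dim(h), c(400L, 3L))  # time column + 2 synergies
  back <- read_decomposition(dir, prefix = "TOY")
  expect_lt(max(abs(back$W - dec$W)), 1e-9)
  expect_lt(max(abs(back$H - dec$H)), 1e-9)
  expect_equal(back$R2, dec$R2)
  expect_equal(back$iterations, dec$iterations)
  empty <- synergait:::new_decomposition(W[, 0, drop = FALSE],
                                         H[0, , drop = FALSE],
                                         R2 = NA, iterations = 0)
  expect_error(write_decomposition(empty, dir), "empty")
})

test_that("the RData list adapter reads deposited-style trials", {
  time <- seq(0, 0.01, by = 5e-4)
  ch <- as.data.frame(matrix(rnorm(length(time) * 12), ncol = 12))
  names(ch) <- SYNERGAIT_MUSCLES
  trials <- list(RAW_EMG_P03_R_30 = cbind(time = time, ch))
  cycles <- list(CYCLE_TIMES_P03_R_30 = data.frame(touchdown = c(0, 1),
                                                   stance = c(0.6, 0.6)))
  d <- withr::local_tempdir()
  save(trials, file = file.path(d, "RAW_EMG.RData"))
  save(cycles, file = file.path(d, "CYCLE_TIMES.RData"))
  expect_equal(read_rdata_trial(file.path(d, "RAW_EMG.RData")),
               "RAW_EMG_P03_R_30")
  emg <- read_rdata_trial(file.path(d, "RAW_EMG.RData"), "RAW_EMG_P03_R_30")
  expect_s3_class(emg, "raw_emg")
  expect_equal(as.matrix(emg$channels), as.matrix(ch), ignore_attr = TRUE)
  ev <- read_rdata_trial(file.path(d, "CYCLE_TIMES.RData"),
                         "CYCLE_TIMES_P03_R_30", type = "cycle_times")
  expect_s3_class(ev, "gait_events")
  expect_error(read_rdata_trial(file.path(d, "RAW_EMG.RData"), "NOPE"),
               "not found")
})
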