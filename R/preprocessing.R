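#' Compute the linear envelope of raw EMG
#'
#' Standard envelope chain: zero-phase high-pass filtering, full-wave
#' rectification, zero-phase low-pass filtering. Both filters are 4th-order
#' IIR Butterworth designs applied forward and backward
#' ([signal::filtfilt()]), so the effective magnitude response is the
#' squared Butterworth response and the phase is zero. Small negative
#' excursions produced by low-pass ringing are clipped to zero so the
#' envelope stays nonnegative for factorization.
#'
#' @param raw A [raw_emg] object.
#' @param hp_cutoff High-pass cutoff in Hz (default 50).
#' @param lp_cutoff Low-pass cutoff in Hz (default 20, the envelope cutoff).
#' @param order Butterworth order (default 4).
#' @return An `emg_envelope` object: `time`, nonnegative `channels`, `fs`.
#' @export
filter_emg <- function(raw, hp_cutoff = 50, lp_cutoff = 20, order = 4) {
  stopifnot(inherits(raw, "raw_emg"))
  fs <- raw$fs
  if (fs <= 2 * hp_cutoff)
    stop(sprintf("sampling rate %.6g Hz too low for a %g Hz high-pass filter", fs, hp_cutoff))
  dur <- diff(range(raw$time))
  if (dur < 10 / min(hp_cutoff, lp_cutoff))
    warning("trial much shorter than the filter settling time; envelope edges unreliable")
  hp <- signal::butter(order, hp_cutoff / (fs / 2), type = "high")
  lp <- signal::butter(order, lp_cutoff / (fs / 2), type = "low")
  env <- vapply(raw$channels, function(x) {
    y <- abs(signal::filtfilt(hp, x))
    pmax(signal::filtfilt(lp, y), 0)
  }, numeric(length(raw$time)))
  env <- as.data.frame(env)
  names(env) <- names(raw$channels)
  structure(list(time = raw$time, channels = env, fs = fs),
            class = "emg_envelope")
}

#' Normalize each EMG channel to its own trial extremes
#'
#' Per channel, subtracts the trial minimum and divides by the range, so
#' that every non-constant channel spans exactly \[0, 1\]. Constant
#' (degenerate) channels are set to all zeros and flagged rather than
#' dropped, keeping the 12-muscle matrix shape stable.
#'
#' @param env An `emg_envelope` from [filter_emg()].
#' @return The envelope with normalized channels and a logical
#'   `degenerate` attribute named by muscle.
#' @export
normalize_amplitude <- function(env) {
  stopifnot(inherits(env, "emg_envelope"))
  degen <- logical(ncol(env$channels))
  names(degen) <- names(env$channels)
  for (j in seq_along(env$channels)) {
    x <- env$channels[[j]]
    rng <- range(x)
    if (rng[2] - rng[1] <= 0) {
      env$channels[[j]] <- rep(0, length(x))
      degen[j] <- TRUE
      warning("channel ", names(env$channels)[j],
              " is constant; set to zero and flagged degenerate")
    } else {
      env$channels[[j]] <- (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  attr(env, "degenerate") <- degen
  env
}

#' Time-normalize envelopes onto the 200-point gait cycle
#'
#' Resamples each gait cycle to 200 points by linear interpolation on the
#' cycle's own time base, assigning 100 points to the stance phase (from
#' touchdown to lift-off) and 100 points to the swing phase (from lift-off
#' to the next touchdown), and concatenates cycles in order. The result is
#' the nonnegative m x n matrix factorized by [extract_synergies()]
#' (m = 12 muscles, n = 200 x cycles).
#'
#' @param env An `emg_envelope`, normally after [normalize_amplitude()].
#' @param events A [gait_events] object.
#' @param n_cycles Number of gait cycles to keep (default 30). Fewer
#'   complete cycles than requested produce a warning, not an error.
#' @param points_per_phase Points per stance and per swing phase (default 100).
#' @return A `normalized_emg` object with elements `V` (12 x n matrix, one
#'   row per muscle), `n_cycles` (cycles actually used), `points_per_phase`
#'   and `muscles`.
#' @export
time_normalize <- function(env, events, n_cycles = 30,
                           points_per_phase = 100) {
  stopifnot(inherits(env, "emg_envelope"), inherits(events, "gait_events"))
  td <- events$touchdowns
  st <- events$stance_durations
  t_end <- max(env$time)
  # a complete cycle needs its closing touchdown inside the recording
  n_avail <- 0L
  for (i in seq_len(length(td) - 1L)) {
    if (td[i + 1L] <= t_end) n_avail <- i else break
  }
  if (n_avail < 1L) stop("no complete gait cycle inside the recording")
  use <- min(n_cycles, n_avail)
  if (use < n_cycles)
    warning(sprintf("only %d of %d requested cycles fit in the recording", use, n_cycles))
  ppc <- 2L * points_per_phase
  mus <- names(env$channels)
  V <- matrix(0, nrow = length(mus), ncol = ppc * use,
              dimnames = list(mus, NULL))
  for (i in seq_len(use)) {
    a <- td[i]; b <- td[i] + st[i]; c_ <- td[i + 1L]
    for (ph in 1:2) {
      lo <- if (ph == 1) a else b
      hi <- if (ph == 1) b else c_
      if (sum(env$time >= lo & env$time <= hi) < 2)
        stop(sprintf("fewer than 2 samples in %s phase of cycle %d",
                     c("stance", "swing")[ph], i))
      xout <- seq(lo, hi, length.out = points_per_phase)
      cols <- (i - 1L) * ppc + (ph - 1L) * points_per_phase +
        seq_len(points_per_phase)
      for (m in seq_along(mus))
        V[m, cols] <- approx(env$time, env$channels[[m]], xout = xout,
                             rule = 2)$y
    }
  }
  structure(list(V = V, n_cycles = use, points_per_phase = points_per_phase,
                 muscles = mus,
                 degenerate = attr(env, "degenerate")),
            class = "normalized_emg")
}

#' @export
print.normalized_emg <- function(x, ...) {
  cat(sprintf("<normalized_emg> %d muscles x %d points (%d cycles of %d)\n",
              nrow(x$V), ncol(x$V), x$n_cycles, 2 * x$points_per_phase))
  invisible(x)
}

#' Force recording container
#'
#' @param time Sample times in seconds (uniform).
#' @param fz Vertical ground-reaction force in N.
#' @param cop_ap Optional anterior-posterior center of pressure in m.
#' @return An object of class `force_recording`.
#' @export
force_recording <- function(time, fz, cop_ap = NULL) {
  if (length(time) != length(fz))
    stop("`time` and `fz` must have equal length")
  if (!all(is.finite(fz))) stop("`fz` must be finite")
  dt <- diff(time)
  if (any(dt <= 0) || (length(dt) && max(abs(dt - median(dt))) > 1e-6 * median(dt)))
    stop("`time` must be strictly increasing and uniform")
  structure(list(time = as.numeric(time), fz = as.numeric(fz),
                 cop_ap = cop_ap, fs = 1 / median(dt)),
            class = "force_recording")
}

#' Detect gait events from a vertical force trace
#'
#' Simple threshold detector: a stance phase is a contiguous run of samples
#' with `fz > threshold` lasting at least `min_contact` seconds. Touchdown
#' is the first sample of the run, lift-off the last; shorter runs (noise
#' spikes) are ignored.
#'
#' @param force A [force_recording].
#' @param threshold Force threshold in N (default 30).
#' @param min_contact Minimum contact duration in s (default 0.05).
#' @return A [gait_events] object (possibly empty, with a warning).
#' @export
detect_gait_events <- function(force, threshold = 30, min_contact = 0.05) {
  stopifnot(inherits(force, "force_recording"))
  above <- force$fz > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  td <- numeric(0); st <- numeric(0)
  for (i in keep) {
    t0 <- force$time[starts[i]]
    t1 <- force$time[ends[i]]
    if (t1 - t0 >= min_contact) {
      td <- c(td, t0)
      st <- c(st, t1 - t0)
    }
  }
  if (!length(td)) {
    warning("no super-threshold contact found; returning empty gait events")
    return(structure(list(touchdowns = numeric(0),
                          stance_durations = numeric(0)),
                     class = "gait_events"))
  }
  gait_events(td, st)
}

#' Spatiotemporal gait parameters from gait events
#'
#' Cycle duration is the interval between successive touchdowns of the same
#' limb; cadence counts two steps per gait cycle, so
#' cadence = 120 / mean cycle duration (steps/min).
#'
#' @param events A [gait_events] with at least two touchdowns.
#' @return A `gait_parameters` object: `cadence` (steps/min), `stance_time`
#'   (s), `swing_time` (s), `n_cycles`.
#' @export
compute_gait_parameters <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  td <- events$touchdowns
  if (length(td) < 2) stop("at least two touchdowns are required")
  cyc <- diff(td)
  st <- events$stance_durations[seq_along(cyc)]
  sw <- cyc - st
  if (any(sw <= 0)) stop("nonpositive swing time: stance exceeds cycle duration")
  structure(list(cadence = 120 / mean(cyc),
                 stance_time = mean(events$stance_durations),
                 swing_time = mean(sw),
                 n_cycles = length(cyc)),
            class = "gait_parameters")
}

#' @export
print.gait_parameters <- function(x, ...) {
  cat(sprintf("<gait_parameters> cadence %.1f steps/min, stance %.3f s, swing %.3f s (%d cycles)\n",
              x$cadence, x$stance_time, x$swing_time, x$n_cycles))
  invisible(x)
}

#' Foot strike index and strike pattern
#'
#' The strike index is the distance from the heel to the center of pressure
#' at impact, relative to total foot length: 0 marks the most posterior and
#' 1 the most anterior point of the shoe. Values up to 0.33 indicate a
#' rearfoot strike; 0.34-1.00 a mid/forefoot strike.
#'
#' @param heel_pos Heel position at impact (m).
#' @param cop_at_impact Center-of-pressure position at impact (m), on the
#'   same axis as `heel_pos`; clipped into the foot span with a warning if
#'   slightly outside.
#' @param foot_length Total foot length (m), positive.
#' @return A list with `strike_index` in \[0, 1\] and `strike_pattern`
#'   (`"rearfoot"` or `"mid_forefoot"`).
#' @export
compute_strike_index <- function(heel_pos, cop_at_impact, foot_length) {
  if (!is.numeric(foot_length) || foot_length <= 0)
    stop("`foot_length` must be positive")
  si <- (cop_at_impact - heel_pos) / foot_length
  if (si < 0 || si > 1) {
    warning("center of pressure outside the foot span; clipping strike index")
    si <- min(max(si, 0), 1)
  }
  si <- abs(si)
  list(strike_index = si,
       strike_pattern = if (si <= 0.33) "rearfoot" else "mid_forefoot")
}
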