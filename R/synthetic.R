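#' Specification of a synthetic modular gait-EMG trial
#'
#' Collects the ground-truth parameters of the generator: a modular
#' envelope model in which each of `rank` synergies contributes a
#' Gaussian-bump motor primitive (one bump per gait cycle, wrapped on the
#' 200-point cycle) mixed into 12 muscle channels through a nonnegative
#' module matrix, with cycle-to-cycle phase jitter and additive noise.
#'
#' Defaults emulate a 30-cycle treadmill trial: four synergies peaking at
#' points 25, 75, 125 and 175 of the 200-point cycle (weight acceptance,
#' propulsion, early swing, late swing), bump width sigma = 18 points
#' (FWHM about 42 points), jitter sd 2 points, additive noise sd 0.02,
#' stance fraction 0.6 of a 1 s cycle, EMG at 2 kHz.
#'
#' @param n_muscles Number of EMG channels (fixed at 12 for the canonical
#'   muscle set).
#' @param n_cycles Gait cycles per trial (default 30).
#' @param rank Number of ground-truth synergies (default 4).
#' @param primitive_centers Peak phases in \[0, 200) per synergy.
#' @param primitive_widths Gaussian sigma in points per synergy (scalar
#'   recycled).
#' @param width_scale Multiplicative width factor, a "speed" surrogate:
#'   larger values produce wider, less complex primitives.
#' @param module_matrix `"G1-like"`, `"G2-like"`, or an explicit
#'   nonnegative `n_muscles` x `rank` matrix.
#' @param cycle_jitter_sd Cycle-to-cycle jitter of bump centers, in points.
#' @param noise_sd Additive Gaussian noise sd on the envelope (amplitude
#'   fraction).
#' @param blend_fraction Probability that a trial carries a planted
#'   combined synergy (one primitive replaced by a sum of two bumps).
#' @param stance_fraction Stance share of the cycle duration.
#' @param cycle_duration Gait cycle duration in seconds.
#' @param emg_sampling_rate EMG sampling rate in Hz.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A validated `synth_spec` object.
#' @export
synth_spec <- function(n_muscles = 12, n_cycles = 30, rank = 4,
                       primitive_centers = c(25, 75, 125, 175),
                       primitive_widths = 18, width_scale = 1,
                       module_matrix = "G1-like", cycle_jitter_sd = 2,
                       noise_sd = 0.02, blend_fraction = 0,
                       stance_fraction = 0.6, cycle_duration = 1.0,
                       emg_sampling_rate = 2000, seed = NULL) {
  if (rank > n_muscles) stop("`rank` must not exceed `n_muscles`")
  if (length(primitive_centers) != rank)
    stop("`primitive_centers` must supply one phase per synergy")
  primitive_widths <- rep_len(primitive_widths, rank)
  if (any(primitive_widths <= 0) || width_scale <= 0)
    stop("primitive widths must be positive")
  if (blend_fraction < 0 || blend_fraction > 1)
    stop("`blend_fraction` must be in [0, 1]")
  if (stance_fraction <= 0 || stance_fraction >= 1)
    stop("`stance_fraction` must be in (0, 1)")
  structure(list(n_muscles = n_muscles, n_cycles = n_cycles, rank = rank,
                 primitive_centers = primitive_centers,
                 primitive_widths = primitive_widths,
                 width_scale = width_scale, module_matrix = module_matrix,
                 cycle_jitter_sd = cycle_jitter_sd, noise_sd = noise_sd,
                 blend_fraction = blend_fraction,
                 stance_fraction = stance_fraction,
                 cycle_duration = cycle_duration,
                 emg_sampling_rate = emg_sampling_rate, seed = seed),
            class = "synth_spec")
}

# one wrapped Gaussian bump on the npts-point cycle circle: the sum of
# periodic images keeps the curve smooth across the cycle boundary (a
# minimal-distance wrap would leave a derivative kink at the antipode)
.bump <- function(center, sigma, npts = 200) {
  t <- 0:(npts - 1)
  b <- numeric(npts)
  for (k in -2:2) b <- b + exp(-(t - center + k * npts)^2 / (2 * sigma^2))
  b / max(b)
}

.make_primitives_impl <- function(spec, npts = 200) {
  r <- spec$rank
  sig <- spec$primitive_widths * spec$width_scale
  if (any(sig > npts / 3))
    warning("bump width approaches the cycle length; primitives nearly constant")
  H <- matrix(0, r, npts * spec$n_cycles)
  for (cyc in seq_len(spec$n_cycles)) {
    cols <- (cyc - 1L) * npts + seq_len(npts)
    for (s in seq_len(r)) {
      jit <- if (spec$cycle_jitter_sd > 0) rnorm(1, 0, spec$cycle_jitter_sd) else 0
      H[s, cols] <- .bump(spec$primitive_centers[s] + jit, sig[s], npts)
    }
  }
  H
}

#' Generate ground-truth motor primitives
#'
#' One Gaussian bump per synergy and per cycle, centered at the synergy's
#' phase plus seeded cycle-to-cycle jitter, wrapped circularly at the cycle
#' edges (late-swing activity continues into the next touchdown), values in
#' \[0, 1\].
#'
#' @param spec A [synth_spec]; `spec$seed` (if non-`NULL`) seeds the jitter.
#' @return Matrix `rank` x `200 * n_cycles`.
#' @export
make_primitives <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  .make_primitives_impl(spec)
}

#' Ground-truth motor module presets
#'
#' Returns the nonnegative muscle-weight matrix (12 muscles x rank,
#' column maxima 1). The `"G1-like"` preset encodes the module structure of
#' recreational runners (knee/hip extensors in weight acceptance, plantarflexors
#' GM/GL/SO in propulsion, dorsiflexor TA in early swing, hamstrings plus
#' TA in late swing); `"G2-like"` encodes sprinters (GM shifted toward
#' weight acceptance, hamstrings shared between propulsion and late swing,
#' reduced TA in late swing). An explicit matrix is validated and
#' column-normalized to a maximum of 1.
#'
#' @param spec A [synth_spec].
#' @return Matrix `n_muscles` x `rank`, rownames the canonical muscles.
#' @export
make_modules <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  mm <- spec$module_matrix
  if (is.character(mm)) {
    W <- switch(mm,
      "G1-like" = cbind(
        weight_acceptance = c(MA = .90, FL = .50, RF = .80, VM = 1.0, VL = 1.0,
                              ST = .10, BF = .10, TA = .20, PL = .20,
                              GM = .10, GL = .10, SO = .15),
        propulsion        = c(MA = .10, FL = .10, RF = .15, VM = .20, VL = .20,
                              ST = .15, BF = .15, TA = .10, PL = .80,
                              GM = 1.0, GL = .90, SO = 1.0),
        early_swing       = c(MA = .10, FL = .70, RF = .50, VM = .10, VL = .10,
                              ST = .20, BF = .20, TA = 1.0, PL = .30,
                              GM = .05, GL = .05, SO = .05),
        late_swing        = c(MA = .30, FL = .20, RF = .10, VM = .10, VL = .10,
                              ST = 1.0, BF = .90, TA = .60, PL = .20,
                              GM = .05, GL = .05, SO = .05)),
      "G2-like" = cbind(
        weight_acceptance = c(MA = .90, FL = .50, RF = .80, VM = 1.0, VL = 1.0,
                              ST = .10, BF = .10, TA = .20, PL = .20,
                              GM = .80, GL = .30, SO = .30),
        propulsion        = c(MA = .10, FL = .10, RF = .15, VM = .20, VL = .20,
                              ST = .50, BF = .50, TA = .10, PL = .80,
                              GM = .40, GL = .90, SO = 1.0),
        early_swing       = c(MA = .10, FL = .70, RF = .50, VM = .10, VL = .10,
                              ST = .20, BF = .20, TA = 1.0, PL = .30,
                              GM = .05, GL = .05, SO = .05),
        late_swing        = c(MA = .30, FL = .20, RF = .10, VM = .10, VL = .10,
                              ST = 1.0, BF = .90, TA = .30, PL = .20,
                              GM = .05, GL = .05, SO = .05)),
      stop("unknown module preset: ", mm))
    if (spec$rank != ncol(W))
      stop("preset module matrices define 4 synergies; set rank = 4 or pass a matrix")
    if (spec$n_muscles != nrow(W))
      stop("preset module matrices define 12 muscles")
    return(W)
  }
  W <- as.matrix(mm)
  if (nrow(W) != spec$n_muscles || ncol(W) != spec$rank)
    stop("module matrix must be n_muscles x rank")
  if (any(W < 0)) stop("module matrix must be nonnegative")
  mx <- apply(W, 2, max)
  if (any(mx <= 0)) stop("module matrix has an all-zero column")
  sweep(W, 2, mx, "/")
}

#' Synthesize an amplitude/time-normalized EMG matrix with ground truth
#'
#' Builds V = W_true H_true + Gaussian noise, clips negatives, then applies
#' the same per-channel min-subtraction/max-normalization used for real
#' envelopes. With probability `blend_fraction` one synergy's primitive is
#' replaced by the (renormalized) sum of its own bump and another synergy's
#' bump -- a planted combined synergy.
#'
#' @param spec A [synth_spec].
#' @return A list: `V` (a `normalized_emg`) and `truth` (a `ground_truth`
#'   list with `W_true`, `H_true`, `labels`, `combined` flag,
#'   `blended_synergy`).
#' @export
synthesize_normalized_emg <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  H <- .make_primitives_impl(spec)
  W <- make_modules(spec)
  blended <- NA_integer_
  if (spec$blend_fraction > 0 && runif(1) < spec$blend_fraction) {
    blended <- sample(spec$rank, 1)
    partner <- sample(setdiff(seq_len(spec$rank), blended), 1)
    npts <- 200
    for (cyc in seq_len(spec$n_cycles)) {
      cols <- (cyc - 1L) * npts + seq_len(npts)
      mix <- H[blended, cols] + H[partner, cols]
      H[blended, cols] <- mix / max(mix)
    }
  }
  V <- W %*% H
  if (spec$noise_sd > 0)
    V <- V + matrix(rnorm(length(V), 0, spec$noise_sd), nrow(V))
  V[V < 0] <- 0
  for (i in seq_len(nrow(V))) {
    rng <- range(V[i, ])
    if (rng[2] - rng[1] > 0) V[i, ] <- (V[i, ] - rng[1]) / (rng[2] - rng[1])
  }
  rownames(V) <- rownames(W)
  labels <- .planted_labels(spec)
  if (!is.na(blended)) labels[blended] <- "combined"
  nemg <- structure(list(V = V, n_cycles = spec$n_cycles,
                         points_per_phase = 100, muscles = rownames(W),
                         degenerate = setNames(logical(nrow(V)), rownames(W))),
                    class = "normalized_emg")
  truth <- structure(list(W_true = W, H_true = H, labels = labels,
                          combined = !is.na(blended),
                          blended_synergy = blended),
                     class = "ground_truth")
  list(V = nemg, truth = truth)
}

.planted_labels <- function(spec) {
  proto <- .label_prototypes
  vapply(spec$primitive_centers,
         function(p) names(proto)[which.min(abs(proto - p))], character(1))
}

#' Synthesize a raw-like EMG trial with gait events and force trace
#'
#' Maps the ground-truth envelope onto real time (stance spanning
#' `stance_fraction` of each `cycle_duration`), multiplies it onto a
#' band-limited (10-500 Hz) zero-mean carrier to mimic interference-pattern
#' raw EMG, and emits a square-wave vertical force consistent with the gait
#' events (800 N during stance).
#'
#' @param spec A [synth_spec].
#' @return A list: `raw` ([raw_emg]), `events` ([gait_events]), `force`
#'   ([force_recording]), `truth` (as in [synthesize_normalized_emg()],
#'   plus `envelope`, the planted per-muscle envelope in real time).
#' @export
synthesize_raw_trial <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  H <- .make_primitives_impl(spec)
  W <- make_modules(spec)
  fs <- spec$emg_sampling_rate
  cd <- spec$cycle_duration
  st <- spec$stance_fraction * cd
  n_cyc <- spec$n_cycles
  t_end <- n_cyc * cd + st + 0.1 * cd  # covers the closing touchdown's stance
  time <- seq(0, t_end, by = 1 / fs)
  td <- (0:n_cyc) * cd
  events <- gait_events(td, rep(st, n_cyc + 1L))
  # envelope in real time: per cycle, stance maps to points 1..100,
  # swing to points 101..200 of that cycle's primitive block
  env <- matrix(0, length(time), nrow(W))
  E <- t(W %*% H)                      # (200*n_cyc) x muscles
  for (cyc in seq_len(n_cyc)) {
    a <- td[cyc]; b <- a + st; cc <- td[cyc + 1L]
    rows <- (cyc - 1L) * 200L
    for (ph in 1:2) {
      lo <- if (ph == 1) a else b
      hi <- if (ph == 1) b else cc
      sel <- which(time >= lo & time < hi)
      if (!length(sel)) next
      src <- rows + (ph - 1L) * 100L + seq_len(100L)
      u <- (time[sel] - lo) / (hi - lo)           # in [0, 1)
      for (m in seq_len(ncol(env)))
        env[sel, m] <- approx(seq(0, 1, length.out = 100L), E[src, m],
                              xout = u, rule = 2)$y
    }
  }
  bp <- signal::butter(2, c(10, 500) / (fs / 2), type = "pass")
  raw_ch <- matrix(0, length(time), ncol(env))
  for (m in seq_len(ncol(env))) {
    carrier <- signal::filtfilt(bp, rnorm(length(time)))
    raw_ch[, m] <- env[, m] * carrier
  }
  colnames(raw_ch) <- rownames(W)
  raw <- raw_emg(time, raw_ch)
  fz <- numeric(length(time))
  half <- 0.5 / fs   # half-sample tolerance against grid rounding
  for (cyc in seq_len(n_cyc + 1L)) {
    sel <- time >= td[cyc] - half & time <= td[cyc] + st + half
    fz[sel] <- 800
  }
  force <- force_recording(time, fz)
  truth <- structure(list(W_true = W, H_true = H,
                          labels = .planted_labels(spec), combined = FALSE,
                          blended_synergy = NA_integer_,
                          envelope = env),
                     class = "ground_truth")
  list(raw = raw, events = events, force = force, truth = truth)
}
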