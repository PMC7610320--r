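#' Trial metadata
#'
#' Describes one recorded locomotion trial: who, which experimental group,
#' walking or running, belt speed, and acquisition rates.
#'
#' @param participant_code Short participant identifier, e.g. `"P03"`.
#' @param group Experimental group, `"G1"` (walking and submaximal running)
#'   or `"G2"` (submaximal and maximal running).
#' @param locomotion `"W"` (walking) or `"R"` (running).
#' @param speed Belt speed in m/s; must be positive.
#' @param emg_sampling_rate EMG acquisition rate in Hz (default 2000). Must
#'   exceed twice the 500 Hz upper band-pass cutoff of the acquisition device.
#' @param plate_sampling_rate Pressure/force plate rate in Hz. Defaults to
#'   120 for G1 (pressure plate) and 1000 for G2 (force plate).
#' @param sex,age,height,mass,pb Optional anthropometric fields mirrored from
#'   the deposit metadata layout (sex, years, cm, kg, personal-best time).
#'
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(participant_code, group = c("G1", "G2"),
                       locomotion = c("W", "R"), speed,
                       emg_sampling_rate = 2000, plate_sampling_rate = NULL,
                       sex = NULL, age = NULL, height = NULL, mass = NULL,
                       pb = NULL) {
  group <- match.arg(group)
  locomotion <- match.arg(locomotion)
  stopifnot(is.character(participant_code), length(participant_code) == 1L)
  if (!is.numeric(speed) || length(speed) != 1L || speed <= 0)
    stop("`speed` must be a single positive number (m/s)")
  if (emg_sampling_rate <= 2 * 500)
    stop("`emg_sampling_rate` must exceed 1000 Hz (twice the 500 Hz device band-pass cutoff)")
  if (is.null(plate_sampling_rate))
    plate_sampling_rate <- if (group == "G1") 120 else 1000
  structure(list(participant_code = participant_code, group = group,
                 locomotion = locomotion, speed = speed,
                 emg_sampling_rate = emg_sampling_rate,
                 plate_sampling_rate = plate_sampling_rate,
                 sex = sex, age = age, height = height, mass = mass, pb = pb),
            class = "trial_meta")
}

#' @export
print.trial_meta <- function(x, ...) {
  cat(sprintf("<trial_meta> %s %s %s %.1f m/s (EMG %g Hz, plate %g Hz)\n",
              x$participant_code, x$group, x$locomotion, x$speed,
              x$emg_sampling_rate, x$plate_sampling_rate))
  invisible(x)
}

#' Raw EMG container
#'
#' Holds a uniformly sampled multi-channel raw EMG recording of the 12
#' canonical lower-limb muscles (see [SYNERGAIT_MUSCLES]).
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing with a uniform step.
#' @param channels Data frame or matrix with one named column per muscle;
#'   columns are reordered to the canonical muscle order.
#'
#' @return An object of class `raw_emg` with elements `time` (seconds),
#'   `channels` (data frame, canonical order) and `fs` (sampling rate, Hz).
#' @export
raw_emg <- function(time, channels) {
  channels <- as.data.frame(channels)
  .check_channels(names(channels))
  channels <- channels[SYNERGAIT_MUSCLES]
  if (length(time) != nrow(channels))
    stop("`time` and `channels` must have the same number of samples")
  if (anyNA(time) || anyNA(channels))
    stop("raw EMG must not contain missing samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop("`time` must be strictly increasing")
  step <- median(dt)
  if (length(dt) && max(abs(dt - step)) > 1e-6 * step)
    stop("non-uniform sampling: time step deviates by more than 1 ppm")
  structure(list(time = as.numeric(time), channels = channels,
                 fs = 1 / step),
            class = "raw_emg")
}

.check_channels <- function(nms) {
  missing <- setdiff(SYNERGAIT_MUSCLES, nms)
  extra <- setdiff(nms, SYNERGAIT_MUSCLES)
  if (length(missing) || length(extra)) {
    msg <- "channel set mismatch:"
    if (length(missing))
      msg <- paste0(msg, " missing [", paste(missing, collapse = ", "), "]")
    if (length(extra))
      msg <- paste0(msg, " unexpected [", paste(extra, collapse = ", "), "]")
    stop(msg)
  }
  invisible(TRUE)
}

#' @export
print.raw_emg <- function(x, ...) {
  cat(sprintf("<raw_emg> %d samples x 12 muscles @ %.6g Hz (%.3f s)\n",
              length(x$time), x$fs, diff(range(x$time))))
  invisible(x)
}

#' Gait events container
#'
#' Touchdown times and stance durations of one limb. Each stance must fit
#' inside its own gait cycle (i.e. be shorter than the interval to the next
#' touchdown).
#'
#' @param touchdowns Strictly increasing touchdown times in seconds.
#' @param stance_durations Stance-phase durations in seconds, one per
#'   touchdown.
#'
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(touchdowns, stance_durations) {
  touchdowns <- as.numeric(touchdowns)
  stance_durations <- as.numeric(stance_durations)
  if (length(touchdowns) != length(stance_durations))
    stop("`touchdowns` and `stance_durations` must have equal length")
  if (length(touchdowns) > 1 && any(diff(touchdowns) <= 0))
    stop("`touchdowns` must be strictly increasing")
  if (any(stance_durations <= 0))
    stop("stance durations must be positive")
  n <- length(touchdowns)
  if (n > 1) {
    cyc <- diff(touchdowns)
    bad <- which(stance_durations[-n] >= cyc)
    if (length(bad))
      stop(sprintf("stance duration >= cycle duration at cycle %s",
                   paste(bad - 1L, collapse = ", ")))
  }
  structure(list(touchdowns = touchdowns,
                 stance_durations = stance_durations),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d touchdowns", length(x$touchdowns)))
  if (length(x$touchdowns) > 1)
    cat(sprintf(", mean cycle %.3f s, mean stance %.3f s",
                mean(diff(x$touchdowns)), mean(x$stance_durations)))
  cat("\n")
  invisible(x)
}

#' Read a raw EMG trial from a delimited text file
#'
#' Expects a header naming a `time` column plus the 12 canonical muscle
#' columns (any column order; reordered on read). Sampling must be uniform
#' to within 1 ppm.
#'
#' @param path Path to a CSV file.
#' @param meta Optional [trial_meta]; if given, the sampling rate found in
#'   the file is checked against `meta$emg_sampling_rate` (1 ppm tolerance).
#' @return A [raw_emg] object.
#' @export
read_raw_emg <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop("raw EMG file must contain a 'time' column: ", path)
  out <- raw_emg(df$time, df[setdiff(names(df), "time")])
  if (!is.null(meta) &&
      abs(out$fs - meta$emg_sampling_rate) > 1e-6 * meta$emg_sampling_rate)
    stop(sprintf("sampling rate %.6g Hz does not match metadata (%g Hz)",
                 out$fs, meta$emg_sampling_rate))
  out
}

#' Write a raw EMG trial to CSV
#'
#' @param emg A [raw_emg] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_emg <- function(emg, path) {
  stopifnot(inherits(emg, "raw_emg"))
  df <- cbind(time = emg$time, emg$channels)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read gait-cycle breakdown times
#'
#' Reads a two-column table (`touchdown`, `stance`): touchdown incremental
#' times in seconds and the duration of each stance phase in seconds.
#'
#' @param path Path to a CSV file.
#' @return A [gait_events] object.
#' @export
read_cycle_times <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  if (!all(c("touchdown", "stance") %in% names(df)))
    stop("cycle-times file must have columns 'touchdown' and 'stance': ", path)
  gait_events(df$touchdown, df$stance)
}

#' Write gait-cycle breakdown times to CSV
#'
#' @param events A [gait_events] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cycle_times <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  write.csv(data.frame(touchdown = events$touchdowns,
                       stance = events$stance_durations),
            path, row.names = FALSE)
  invisible(path)
}

#' Write trial metadata as a JSON sidecar
#'
#' Keys mirror the deposit metadata layout: `Code`, `Group`, `Sex`, `Speeds`
#' (locomotion type and speed in 10*m/s, e.g. `"W_14"`), `Age`, `Height`,
#' `Mass`, `PB`, plus acquisition rates.
#'
#' @param meta A [trial_meta] object.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_trial_meta <- function(meta, path) {
  stopifnot(inherits(meta, "trial_meta"))
  x <- list(Code = meta$participant_code, Group = meta$group,
            Sex = meta$sex,
            Speeds = sprintf("%s_%02d", meta$locomotion,
                             as.integer(round(meta$speed * 10))),
            Age = meta$age, Height = meta$height, Mass = meta$mass,
            PB = meta$pb,
            EmgSamplingRate = meta$emg_sampling_rate,
            PlateSamplingRate = meta$plate_sampling_rate)
  jsonlite::write_json(x[!vapply(x, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read trial metadata from a JSON sidecar
#'
#' @param path Path to a JSON file written by [write_trial_meta()].
#' @return A [trial_meta] object.
#' @export
read_trial_meta <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- strsplit(x$Speeds, "_", fixed = TRUE)[[1]]
  trial_meta(participant_code = x$Code, group = x$Group,
             locomotion = sp[1], speed = as.numeric(sp[2]) / 10,
             emg_sampling_rate = x$EmgSamplingRate %||% 2000,
             plate_sampling_rate = x$PlateSamplingRate,
             sex = x$Sex, age = x$Age, height = x$Height, mass = x$Mass,
             pb = x$PB)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist a synergy decomposition as tabular text
#'
#' Writes three files under `dir`: `<prefix>_modules.csv` (12 rows x r
#' synergy columns), `<prefix>_primitives.csv` (one `time` index column plus
#' r synergy columns, one row per normalized time point) and
#' `<prefix>_info.json` (rank, reconstruction R^2, iteration count, seed).
#'
#' @param dec A `decomposition` as returned by [nmf_factorize()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, e.g. `"SYNS_P03_R_30"`.
#' @return The three paths, invisibly.
#' @export
write_decomposition <- function(dec, dir, prefix = "SYNS") {
  stopifnot(inherits(dec, "decomposition"))
  if (nrow(dec$H) == 0 || ncol(dec$H) == 0)
    stop("refusing to write an empty decomposition (H has no entries)")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  syn <- paste0("Syn", seq_len(dec$r))
  w <- as.data.frame(dec$W); names(w) <- syn
  w <- cbind(muscle = rownames(dec$W) %||% SYNERGAIT_MUSCLES[seq_len(nrow(dec$W))], w)
  h <- as.data.frame(t(dec$H)); names(h) <- syn
  h <- cbind(time = seq_len(ncol(dec$H)), h)
  paths <- file.path(dir, paste0(prefix, c("_modules.csv", "_primitives.csv",
                                           "_info.json")))
  write.csv(w, paths[1], row.names = FALSE)
  write.csv(h, paths[2], row.names = FALSE)
  jsonlite::write_json(list(r = dec$r, R2 = dec$R2,
                            iterations = dec$iterations, seed = dec$seed),
                       paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Reload a decomposition written by [write_decomposition()]
#'
#' @param dir Directory holding the files.
#' @param prefix File-name prefix used when writing.
#' @return A `decomposition` object.
#' @export
read_decomposition <- function(dir, prefix = "SYNS") {
  w <- read.csv(file.path(dir, paste0(prefix, "_modules.csv")))
  h <- read.csv(file.path(dir, paste0(prefix, "_primitives.csv")))
  info <- jsonlite::read_json(file.path(dir, paste0(prefix, "_info.json")),
                              simplifyVector = TRUE)
  W <- as.matrix(w[setdiff(names(w), "muscle")])
  rownames(W) <- w$muscle
  H <- t(as.matrix(h[setdiff(names(h), "time")]))
  rownames(H) <- colnames(W)
  new_decomposition(W, H, R2 = info$R2, iterations = info$iterations,
                    seed = info$seed)
}

#' Read one trial from the deposited RData list layout
#'
#' Read-only adapter for archives that store all trials of one kind as the
#' elements of a single R list saved in an `.RData` file, with names such as
#' `"RAW_EMG_P03_R_30"` or `"CYCLE_TIMES_P20_R_20"`. Raw EMG elements are
#' data frames with a `time` column plus 12 muscle columns; cycle-time
#' elements are data frames with `touchdown` and `stance` columns.
#'
#' @param path Path to the `.RData` file.
#' @param trial Name of the list element to extract; if `NULL`, the names of
#'   all available trials are returned instead.
#' @param type `"raw_emg"` or `"cycle_times"`: how to interpret the element.
#' @return A [raw_emg] or [gait_events] object, or a character vector of
#'   trial names when `trial` is `NULL`.
#' @export
read_rdata_trial <- function(path, trial = NULL,
                             type = c("raw_emg", "cycle_times")) {
  type <- match.arg(type)
  env <- new.env(parent = emptyenv())
  nm <- load(path, envir = env)
  if (length(nm) != 1L)
    stop("expected a single list object in ", path)
  trials <- get(nm, envir = env)
  if (!is.list(trials)) stop("object '", nm, "' is not a list of trials")
  if (is.null(trial)) return(names(trials))
  if (!trial %in% names(trials))
    stop("trial '", trial, "' not found in ", path)
  df <- as.data.frame(trials[[trial]])
  switch(type,
         raw_emg = raw_emg(df$time, df[setdiff(names(df), "time")]),
         cycle_times = gait_events(df$touchdown, df$stance))
}
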