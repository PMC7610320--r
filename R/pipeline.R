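#' Pipeline configuration
#'
#' Collects every tunable of the per-trial analysis chain with its standard
#' default: 50/20 Hz 4th-order zero-phase Butterworth filtering, 30 gait
#' cycles of 200 points (100 stance + 100 swing), NMF over candidate ranks
#' 1-9 with 10 restarts, 0.01% R^2 plateau over 20 iterations, rank
#' selection at residual MSE 1e-4, Higuchi kmax 10, FWHM with the
#' at-or-above-half-maximum convention.
#'
#' @param hp_cutoff,lp_cutoff,filter_order Envelope filter settings (Hz, Hz,
#'   order).
#' @param n_cycles,points_per_phase Time-normalization settings.
#' @param max_rank,n_restarts,max_iter,conv_tol,conv_window,mse_threshold
#'   NMF and rank-selection settings.
#' @param kmax Higuchi interval bound.
#' @param fwhm_convention `"ge"` or `"gt"` (see [fwhm_cycle()]).
#' @param force_threshold,min_contact Gait-event detection settings (N, s).
#' @param seed Base seed for all stochastic stages.
#' @return A `synergy_config` list.
#' @export
synergy_config <- function(hp_cutoff = 50, lp_cutoff = 20, filter_order = 4,
                           n_cycles = 30, points_per_phase = 100,
                           max_rank = 9, n_restarts = 10, max_iter = 1000,
                           conv_tol = 1e-4, conv_window = 20,
                           mse_threshold = 1e-4, kmax = 10,
                           fwhm_convention = c("ge", "gt"),
                           force_threshold = 30, min_contact = 0.05,
                           seed = 1L) {
  structure(list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 filter_order = filter_order, n_cycles = n_cycles,
                 points_per_phase = points_per_phase, max_rank = max_rank,
                 n_restarts = n_restarts, max_iter = max_iter,
                 conv_tol = conv_tol, conv_window = conv_window,
                 mse_threshold = mse_threshold, kmax = kmax,
                 fwhm_convention = match.arg(fwhm_convention),
                 force_threshold = force_threshold,
                 min_contact = min_contact, seed = as.integer(seed)),
            class = "synergy_config")
}

.stage <- function(name, id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for trial '%s': %s", name, id,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis chain on one trial
#'
#' Stages: envelope filtering, amplitude normalization, gait-cycle time
#' normalization (skipped when the trial already carries a normalized
#' matrix), synergy extraction with rank selection, Higuchi fractal
#' dimension of the primitives, within-trial functional classification
#' (principal shapes clustered from the trial's own primitives), FWHM of
#' the fundamental primitives, and spatiotemporal gait parameters.
#'
#' @param trial A list describing one trial: either `raw` (a [raw_emg])
#'   plus `events` (a [gait_events]), or `V` (a `normalized_emg`);
#'   optionally `meta` (a [trial_meta]), `force` (a [force_recording], used
#'   to detect events when `events` is absent) and `id`.
#' @param config A [synergy_config].
#' @return A `trial_report`: `id`, `rank`, `R2`, `iterations`, `labels`,
#'   `hfd` (trial value), `per_primitive_hfd`, `fwhm` (named by label,
#'   fundamental synergies only), `gait` (or `NULL`), plus the
#'   `decomposition`, `shapes` and rank-selection `trace`.
#' @export
run_trial <- function(trial, config = synergy_config()) {
  id <- trial$id %||% (if (!is.null(trial$meta))
    trial$meta$participant_code else "trial")
  events <- trial$events
  if (is.null(events) && !is.null(trial$force))
    events <- .stage("detect_gait_events", id,
                     detect_gait_events(trial$force, config$force_threshold,
                                        config$min_contact))
  if (!is.null(trial$V)) {
    V <- trial$V
  } else {
    if (is.null(trial$raw) || is.null(events))
      stop("trial must provide either `V` or `raw` plus `events`/`force`")
    env <- .stage("filter_emg", id,
                  filter_emg(trial$raw, config$hp_cutoff, config$lp_cutoff,
                             config$filter_order))
    env <- .stage("normalize_amplitude", id, normalize_amplitude(env))
    V <- .stage("time_normalize", id,
                time_normalize(env, events, config$n_cycles,
                               config$points_per_phase))
  }
  ext <- .stage("extract_synergies", id,
                extract_synergies(V, base_seed = config$seed,
                                  max_rank = config$max_rank,
                                  n_restarts = config$n_restarts,
                                  max_iter = config$max_iter,
                                  tol = config$conv_tol,
                                  window = config$conv_window,
                                  mse_threshold = config$mse_threshold))
  dec <- ext$decomposition
  hfd <- .stage("trial_hfd", id, trial_hfd(dec, kmax = config$kmax))
  ppc <- 2L * config$points_per_phase
  pool <- .stage("build_primitive_pool", id,
                 build_primitive_pool(dec, points_per_cycle = ppc))
  shapes <- .stage("cluster_principal_shapes", id,
                   cluster_principal_shapes(pool, dec$r,
                                            base_seed = config$seed,
                                            n_restarts = config$n_restarts,
                                            max_iter = config$max_iter,
                                            tol = config$conv_tol,
                                            window = config$conv_window))
  labels <- .stage("assign_labels", id, assign_labels(shapes, pool))
  fw <- .stage("fwhm", id, {
    out <- numeric(0)
    for (s in seq_len(dec$r)) {
      if (labels$label[s] == "combined") next
      res <- fwhm_primitive(dec$H[s, ], points_per_cycle = ppc,
                            convention = config$fwhm_convention)
      out[labels$label[s]] <- res$mean_width
    }
    out
  })
  gait <- if (!is.null(events) && length(events$touchdowns) >= 2)
    .stage("gait_parameters", id, compute_gait_parameters(events)) else NULL
  structure(list(id = id, meta = trial$meta, rank = dec$r, R2 = dec$R2,
                 iterations = dec$iterations, labels = labels$label,
                 hfd = hfd$trial_hfd, per_primitive_hfd = hfd$per_primitive_hfd,
                 fwhm = fw, gait = gait, decomposition = dec,
                 shapes = shapes, trace = ext$trace),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("<trial_report> %s: rank %d (R2 %.3f), HFD %.3f, labels: %s\n",
              x$id, x$rank, x$R2, x$hfd, paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Run the analysis chain on a cohort and aggregate per condition
#'
#' Runs [run_trial()] up to the synergy-extraction and HFD stages for every
#' trial (trial failures are logged as warnings and the trial skipped),
#' then performs the functional classification at condition level: all
#' primitives of one condition (group, locomotion, speed) are pooled,
#' clustered into principal shapes, and labelled together. Returns tidy
#' per-condition summary tables ready for standard statistical tools.
#'
#' @param trials List of trial lists (see [run_trial()]); each must carry a
#'   `meta` ([trial_meta]) so trials can be grouped into conditions.
#' @param config A [synergy_config].
#' @return A `cohort_result`: `trial_table` (per-trial rank, R^2, HFD, gait
#'   parameters), `labels_table` (one row per extracted synergy with its
#'   functional label), `rank_summary` (mean and sd of rank per condition),
#'   `hfd_summary`, `fwhm_table` (per fundamental synergy), the
#'   `occurrence` table, and `combined_fraction` (per locomotion type).
#' @export
run_cohort <- function(trials, config = synergy_config()) {
  if (!length(trials)) stop("no trials supplied")
  reports <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (is.null(tr$meta)) stop("every cohort trial needs `meta`")
    rep_i <- tryCatch(
      run_trial_core(tr, config),
      error = function(e) { warning(conditionMessage(e)); NULL })
    if (!is.null(rep_i)) reports[[length(reports) + 1L]] <- rep_i
  }
  if (!length(reports)) stop("every trial failed")
  meta_df <- do.call(rbind, lapply(reports, function(r)
    data.frame(id = r$id, participant = r$meta$participant_code,
               group = r$meta$group, locomotion = r$meta$locomotion,
               speed = r$meta$speed, rank = r$rank, R2 = r$R2,
               hfd = r$hfd,
               cadence = r$gait$cadence %||% NA_real_,
               stance_time = r$gait$stance_time %||% NA_real_,
               swing_time = r$gait$swing_time %||% NA_real_)))
  conds <- unique(meta_df[c("group", "locomotion", "speed")])
  ppc <- 2L * config$points_per_phase
  labels_rows <- list(); fwhm_rows <- list()
  for (ci in seq_len(nrow(conds))) {
    in_cond <- which(meta_df$group == conds$group[ci] &
                     meta_df$locomotion == conds$locomotion[ci] &
                     meta_df$speed == conds$speed[ci])
    decs <- lapply(reports[in_cond], `[[`, "decomposition")
    names(decs) <- meta_df$id[in_cond]
    pool <- build_primitive_pool(decs, points_per_cycle = ppc)
    shapes <- cluster_principal_shapes(pool, max(meta_df$rank[in_cond]),
                                       base_seed = config$seed,
                                       n_restarts = config$n_restarts,
                                       max_iter = config$max_iter,
                                       tol = config$conv_tol,
                                       window = config$conv_window)
    labs <- assign_labels(shapes, pool)
    pm <- attr(pool, "meta")
    for (k in seq_len(nrow(pool))) {
      ti <- in_cond[match(pm$trial[k], meta_df$id[in_cond])]
      labels_rows[[length(labels_rows) + 1L]] <- data.frame(
        participant = meta_df$participant[ti], group = conds$group[ci],
        locomotion = conds$locomotion[ci], speed = conds$speed[ci],
        trial = pm$trial[k], synergy = pm$synergy[k], label = labs$label[k])
      if (labs$label[k] != "combined") {
        H <- reports[[ti]]$decomposition$H
        fw <- fwhm_primitive(H[pm$synergy[k], ], points_per_cycle = ppc,
                             convention = config$fwhm_convention)
        fwhm_rows[[length(fwhm_rows) + 1L]] <- data.frame(
          participant = meta_df$participant[ti], group = conds$group[ci],
          locomotion = conds$locomotion[ci], speed = conds$speed[ci],
          label = labs$label[k], fwhm = fw$mean_width)
      }
    }
  }
  labels_table <- do.call(rbind, labels_rows)
  fwhm_table <- if (length(fwhm_rows)) do.call(rbind, fwhm_rows) else
    data.frame(participant = character(0), group = character(0),
               locomotion = character(0), speed = numeric(0),
               label = character(0), fwhm = numeric(0))
  agg2 <- function(col, f) {
    d <- meta_df
    d$.y <- meta_df[[col]]
    aggregate(.y ~ group + locomotion + speed, d, f)
  }
  rank_summary <- merge(
    setNames(agg2("rank", mean),
             c("group", "locomotion", "speed", "mean_rank")),
    setNames(agg2("rank", sd),
             c("group", "locomotion", "speed", "sd_rank")))
  hfd_summary <- merge(
    setNames(agg2("hfd", mean),
             c("group", "locomotion", "speed", "mean_hfd")),
    setNames(agg2("hfd", sd),
             c("group", "locomotion", "speed", "sd_hfd")))
  comb <- aggregate(label ~ locomotion, labels_table,
                    function(l) mean(l == "combined"))
  names(comb) <- c("locomotion", "combined_fraction")
  structure(list(trial_table = meta_df, labels_table = labels_table,
                 rank_summary = rank_summary, hfd_summary = hfd_summary,
                 fwhm_table = fwhm_table,
                 occurrence = occurrence_table(labels_table),
                 combined_fraction = comb),
            class = "cohort_result")
}

# per-trial stages shared by run_trial and run_cohort (no classification)
run_trial_core <- function(trial, config) {
  id <- trial$id %||% (if (!is.null(trial$meta))
    trial$meta$participant_code else "trial")
  events <- trial$events
  if (is.null(events) && !is.null(trial$force))
    events <- .stage("detect_gait_events", id,
                     detect_gait_events(trial$force, config$force_threshold,
                                        config$min_contact))
  if (!is.null(trial$V)) {
    V <- trial$V
  } else {
    env <- .stage("filter_emg", id,
                  filter_emg(trial$raw, config$hp_cutoff, config$lp_cutoff,
                             config$filter_order))
    env <- .stage("normalize_amplitude", id, normalize_amplitude(env))
    V <- .stage("time_normalize", id,
                time_normalize(env, events, config$n_cycles,
                               config$points_per_phase))
  }
  ext <- .stage("extract_synergies", id,
                extract_synergies(V, base_seed = config$seed,
                                  max_rank = config$max_rank,
                                  n_restarts = config$n_restarts,
                                  max_iter = config$max_iter,
                                  tol = config$conv_tol,
                                  window = config$conv_window,
                                  mse_threshold = config$mse_threshold))
  dec <- ext$decomposition
  hfd <- .stage("trial_hfd", id, trial_hfd(dec, kmax = config$kmax))
  gait <- if (!is.null(events) && length(events$touchdowns) >= 2)
    compute_gait_parameters(events) else NULL
  list(id = id, meta = trial$meta, rank = dec$r, R2 = dec$R2,
       iterations = dec$iterations, hfd = hfd$trial_hfd, gait = gait,
       decomposition = dec, trace = ext$trace)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d trials, %d conditions\n",
              nrow(x$trial_table), nrow(x$rank_summary)))
  print(x$rank_summary)
  invisible(x)
}

#' Synthesize a cohort of trials
#'
#' Convenience wrapper generating one normalized-matrix trial per
#' participant and condition from a base [synth_spec], with per-trial seeds
#' derived from `base_seed`. `width_scale` may be given per condition to
#' emulate the speed dependence of primitive width.
#'
#' @param n_participants Participants per group (default 15).
#' @param speeds Numeric vector of condition speeds (m/s).
#' @param group,locomotion Condition descriptors applied to all trials.
#' @param base_spec A [synth_spec] supplying all other generator settings.
#' @param width_scales Optional per-speed width factors (recycled).
#' @param base_seed Integer; trial seeds are derived deterministically.
#' @return List of trial lists suitable for [run_cohort()].
#' @export
synthesize_cohort <- function(n_participants = 15, speeds = c(2.8, 4.2),
                              group = "G2", locomotion = "R",
                              base_spec = synth_spec(),
                              width_scales = 1, base_seed = 1L) {
  width_scales <- rep_len(width_scales, length(speeds))
  trials <- list()
  k <- 0L
  for (si in seq_along(speeds)) {
    for (p in seq_len(n_participants)) {
      k <- k + 1L
      spec <- base_spec
      spec$width_scale <- width_scales[si]
      spec$seed <- base_seed + 1000L * si + p
      sim <- synthesize_normalized_emg(spec)
      code <- sprintf("P%02d", p)
      trials[[k]] <- list(
        id = sprintf("%s_%s_%02d", code, locomotion,
                     as.integer(round(speeds[si] * 10))),
        V = sim$V, truth = sim$truth,
        meta = trial_meta(code, group = group, locomotion = locomotion,
                          speed = speeds[si]))
    }
  }
  trials
}
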