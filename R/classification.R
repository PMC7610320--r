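#' Build a pool of mean-cycle motor primitives
#'
#' Reduces every primitive of every decomposition to its mean gait cycle
#' (average over the concatenated cycles), subtracts the minimum and
#' normalizes to the maximum. The pooled rows are the input to
#' [cluster_principal_shapes()]. Constant primitives become zero rows and
#' are flagged.
#'
#' @param decompositions A `decomposition` or (optionally named) list of
#'   decompositions from one condition set.
#' @param points_per_cycle Points per gait cycle (default 200).
#' @return A numeric pool matrix (primitives x `points_per_cycle`) with
#'   attributes `meta` (data frame: `trial`, `synergy`) and `degenerate`
#'   (logical per row).
#' @export
build_primitive_pool <- function(decompositions, points_per_cycle = 200) {
  if (inherits(decompositions, "decomposition"))
    decompositions <- list(decompositions)
  if (!length(decompositions)) stop("empty input: no decompositions to pool")
  nms <- names(decompositions) %||% paste0("trial", seq_along(decompositions))
  rows <- list(); trial <- character(0); synergy <- integer(0)
  for (d in seq_along(decompositions)) {
    H <- decompositions[[d]]$H
    if (ncol(H) %% points_per_cycle != 0)
      stop("primitive length is not a multiple of `points_per_cycle`")
    for (s in seq_len(nrow(H))) {
      cyc <- matrix(H[s, ], nrow = points_per_cycle)
      mc <- rowMeans(cyc)
      rows[[length(rows) + 1L]] <- mc
      trial <- c(trial, nms[d]); synergy <- c(synergy, s)
    }
  }
  pool <- do.call(rbind, rows)
  degen <- logical(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    rng <- range(pool[i, ])
    if (rng[2] - rng[1] <= 0) {
      pool[i, ] <- 0
      degen[i] <- TRUE
      warning("primitive ", i, " in the pool is constant; zeroed and flagged")
    } else {
      pool[i, ] <- (pool[i, ] - rng[1]) / (rng[2] - rng[1])
    }
  }
  attr(pool, "meta") <- data.frame(trial = trial, synergy = synergy)
  attr(pool, "degenerate") <- degen
  pool
}

#' Cluster pooled primitives into principal shapes
#'
#' Runs the same NMF machinery used for synergy extraction on the
#' transposed pool (time points x primitives), with candidate ranks from 1
#' to the maximum observed factorization rank plus one and the same
#' linear-fit rank-selection rule. The resulting basis curves are the
#' "principal shapes"; the coefficients give each primitive's weight on
#' each shape. Shapes are rescaled to a maximum of 1 (the compensating
#' factor is absorbed into the weights, leaving the reconstruction
#' unchanged).
#'
#' @param pool Pool matrix from [build_primitive_pool()].
#' @param max_rank_observed Maximum factorization rank observed across the
#'   pooled trials.
#' @param base_seed Seed for the NMF restart sweep.
#' @param n_restarts Restarts per candidate rank (default 10).
#' @param ... Passed on to [extract_synergies()].
#' @return A `principal_shapes` object: `shapes` (n_shapes x time points,
#'   each row max 1), `weights` (n_primitives x n_shapes),
#'   `functional_order` (label per shape, via [label_by_function()]),
#'   `trace` (rank-selection trace).
#' @export
cluster_principal_shapes <- function(pool, max_rank_observed, base_seed = 1L,
                                     n_restarts = 10, ...) {
  if (any(pool < 0)) stop("pool must be nonnegative")
  ext <- extract_synergies(t(pool), base_seed = base_seed,
                           max_rank = max_rank_observed + 1L,
                           n_restarts = n_restarts, ...)
  W <- ext$decomposition$W          # time points x n_shapes basis curves
  H <- ext$decomposition$H          # n_shapes x n_primitives coefficients
  for (j in seq_len(ncol(W))) {
    a <- max(W[, j])
    if (a > 0) { W[, j] <- W[, j] / a; H[j, ] <- H[j, ] * a }
  }
  shapes <- t(W)
  structure(list(shapes = shapes, weights = t(H),
                 functional_order = label_by_function(shapes),
                 trace = ext$trace),
            class = "principal_shapes")
}

#' @export
print.principal_shapes <- function(x, ...) {
  cat(sprintf("<principal_shapes> %d shapes over %d points: %s\n",
              nrow(x$shapes), ncol(x$shapes),
              paste(x$functional_order, collapse = ", ")))
  invisible(x)
}

#' Order principal shapes by locomotor function
#'
#' Assigns each shape one of the four fundamental functions from the phase
#' of its activation peak within the 200-point cycle (stance = points
#' 1-100, inclusive; swing = 101-200): weight acceptance and propulsion
#' peak in early and late stance, early and late swing in early and late
#' swing. Shapes are matched greedily to the prototype peak phases
#' (25, 75, 125, 175), closest pair first, so the rule also covers
#' conditions where fewer than four shapes are present; distance ties
#' prefer the stance-side (earlier) prototype. Two shapes with an
#' identical peak index are disambiguated by their center-of-mass index.
#'
#' @param shapes Matrix of shapes (rows) over the normalized cycle, or a
#'   `principal_shapes` object.
#' @return Character vector: one functional label per shape.
#' @export
label_by_function <- function(shapes) {
  if (inherits(shapes, "principal_shapes")) shapes <- shapes$shapes
  shapes <- as.matrix(shapes)
  ns <- nrow(shapes); np <- ncol(shapes)
  if (ns < 1) stop("need at least one shape")
  # 0-based peak phase so positions line up with the cycle phase axis
  pos <- vapply(seq_len(ns), function(i) which.max(shapes[i, ]), integer(1))
  pos <- as.numeric(pos) - 1
  dup <- duplicated(pos) | duplicated(pos, fromLast = TRUE)
  if (any(dup)) {
    message("shapes with identical peak index; breaking ties by center of mass")
    for (i in which(dup)) {
      x <- shapes[i, ]
      if (sum(x) > 0) pos[i] <- sum((seq_len(np) - 1) * x) / sum(x)
    }
  }
  proto <- .label_prototypes * (np / 200)   # scale prototypes to the grid
  D <- abs(outer(pos, proto, "-"))
  labels <- rep(NA_character_, ns)
  free <- rep(TRUE, length(proto))
  todo <- rep(TRUE, ns)
  while (any(todo) && any(free)) {
    Dm <- D
    Dm[!todo, ] <- Inf
    Dm[, !free] <- Inf
    j <- which(Dm == min(Dm), arr.ind = TRUE)
    # distance ties: prefer the stance-side (lower-index) prototype
    j <- j[order(j[, 2], j[, 1]), , drop = FALSE][1, ]
    labels[j[1]] <- names(proto)[j[2]]
    todo[j[1]] <- FALSE
    free[j[2]] <- FALSE
  }
  if (any(todo))  # more shapes than prototypes: nearest label, duplicated
    for (i in which(todo)) labels[i] <- names(proto)[which.min(D[i, ])]
  labels
}

#' Classify pooled primitives as fundamental or combined
#'
#' Two-step rule. Step 1: a primitive's candidate shape is the one carrying
#' its largest NMF weight; the primitive is admitted only if that weight is
#' at least the average of all entries of the weight matrix. Step 2: the
#' R^2 between the (normalized) primitive and its candidate shape must be
#' at least 25% of the average R^2 obtained by the other admitted
#' primitives against their own shapes (four times that average when it is
#' negative). Admitted primitives that pass both steps inherit the
#' functional label of their shape; all others are labelled `"combined"`.
#'
#' @param shapes A `principal_shapes` object from
#'   [cluster_principal_shapes()] (built from the same pool).
#' @param pool The pool matrix the shapes were clustered from.
#' @return A `synergy_labels` object: `label` (character per primitive),
#'   `shape` (candidate shape index), `r2` (step-2 R^2, `NA` where not
#'   reached) and the pool `meta`.
#' @export
assign_labels <- function(shapes, pool) {
  stopifnot(inherits(shapes, "principal_shapes"))
  Wt <- shapes$weights
  if (nrow(Wt) != nrow(pool))
    stop("weights and pool disagree on the number of primitives")
  n <- nrow(pool)
  degen <- attr(pool, "degenerate") %||% logical(n)
  cand <- apply(Wt, 1, which.max)
  wbar <- mean(Wt)
  admitted <- Wt[cbind(seq_len(n), cand)] >= wbar & !degen
  if (!any(admitted))
    warning("no primitive passed the weight criterion; all labelled combined")
  shape_cmp <- t(apply(shapes$shapes, 1, function(s) {
    rng <- range(s)
    if (rng[2] - rng[1] <= 0) s else (s - rng[1]) / (rng[2] - rng[1])
  }))
  r2 <- rep(NA_real_, n)
  for (i in which(admitted))
    r2[i] <- r_squared(pool[i, ], shape_cmp[cand[i], ])
  label <- rep("combined", n)
  for (i in which(admitted)) {
    others <- r2[admitted & seq_len(n) != i]
    ok <- if (!length(others)) TRUE else {
      ref <- mean(others)
      if (ref >= 0) r2[i] >= 0.25 * ref else r2[i] >= 4 * ref
    }
    if (ok) label[i] <- shapes$functional_order[cand[i]]
  }
  structure(list(label = label, shape = cand, r2 = r2,
                 meta = attr(pool, "meta")),
            class = "synergy_labels")
}

#' @export
print.synergy_labels <- function(x, ...) {
  tab <- table(factor(x$label, levels = SYNERGY_LABELS))
  cat("<synergy_labels>", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Frequency of occurrence of fundamental synergies
#'
#' Counts, per condition (group, locomotion, speed) and fundamental
#' function, the number of distinct participants exhibiting at least one
#' synergy with that label.
#'
#' @param labels_df Data frame with columns `participant`, `group`,
#'   `locomotion`, `speed` and `label` (one row per extracted synergy).
#' @return Data frame with one row per condition and one count column per
#'   fundamental label.
#' @export
occurrence_table <- function(labels_df) {
  need <- c("participant", "group", "locomotion", "speed", "label")
  if (!all(need %in% names(labels_df)))
    stop("`labels_df` must have columns ", paste(need, collapse = ", "))
  conds <- unique(labels_df[c("group", "locomotion", "speed")])
  conds <- conds[order(conds$group, conds$locomotion, conds$speed), ,
                 drop = FALSE]
  fund <- setdiff(SYNERGY_LABELS, "combined")
  out <- conds
  for (lab in fund) out[[lab]] <- NA_integer_
  for (i in seq_len(nrow(conds))) {
    sub <- labels_df[labels_df$group == conds$group[i] &
                     labels_df$locomotion == conds$locomotion[i] &
                     labels_df$speed == conds$speed[i], ]
    for (lab in fund)
      out[[lab]][i] <- length(unique(sub$participant[sub$label == lab]))
  }
  rownames(out) <- NULL
  out
}
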