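new_decomposition <- function(W, H, R2, iterations, seed = NA_integer_,
                              r2_trace = NULL) {
  structure(list(W = W, H = H, r = ncol(W), R2 = R2,
                 iterations = iterations, seed = seed, r2_trace = r2_trace),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> rank %d, R2 = %.4f, %d iterations (seed %s)\n",
              x$r, x$R2, x$iterations, format(x$seed)))
  invisible(x)
}

.as_V <- function(V) {
  if (inherits(V, "normalized_emg")) V <- V$V
  V <- as.matrix(V)
  if (anyNA(V)) stop("V must not contain missing values")
  if (any(V < 0)) stop("V must be nonnegative")
  if (all(V == 0)) stop("V is all zero; nothing to factorize")
  V
}

#' Coefficient of determination between two matrices
#'
#' Treats both matrices as single pooled data sets:
#' R^2 = 1 - sum((V - VR)^2) / sum((V - mean(V))^2), where the variance is
#' taken about the grand mean of `V` over all entries. Reconstructions worse
#' than the grand mean yield negative values.
#'
#' @param V Reference matrix.
#' @param VR Reconstructed matrix of the same shape.
#' @return A single numeric value, at most 1.
#' @export
r_squared <- function(V, VR) {
  V <- as.matrix(V); VR <- as.matrix(VR)
  if (!all(dim(V) == dim(VR))) stop("V and VR must have the same shape")
  sst <- sum((V - mean(V))^2)
  if (sst == 0) stop("V has zero total variance; R^2 undefined")
  1 - sum((V - VR)^2) / sst
}

#' Factorize an EMG matrix into motor modules and primitives
#'
#' Non-negative matrix factorization V ~ W H by multiplicative updates for
#' the Gaussian (Frobenius) objective. Each iteration updates H using the
#' current W, then W using the freshly updated H; both matrices stay
#' nonnegative by construction. After each iteration the reconstruction
#' R^2 between V and W H is computed; the factorization stops when the
#' relative change in R^2 over the last `window` iterations falls below
#' `tol` (0.01% by default) or after `max_iter` iterations.
#'
#' W and H are initialized uniformly at random in (0, 1) from `seed`, so a
#' fixed seed gives a bit-identical decomposition.
#'
#' @param V A `normalized_emg` or nonnegative numeric matrix (muscles x
#'   time points).
#' @param r Factorization rank (number of synergies), at least 1.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Iteration cap (default 1000).
#' @param tol Relative R^2 plateau tolerance (default 1e-4, i.e. 0.01%).
#' @param window Plateau look-back window in iterations (default 20).
#' @param eps Denominator guard added to both update rules (default 1e-12).
#' @return A `decomposition`: `W` (m x r motor modules), `H` (r x n motor
#'   primitives), `r`, `R2`, `iterations`, `seed`.
#' @export
nmf_factorize <- function(V, r, seed = 1L, max_iter = 1000, tol = 1e-4,
                          window = 20, eps = 1e-12) {
  V <- .as_V(V)
  if (!is.numeric(r) || length(r) != 1L || r < 1)
    stop("`r` must be a positive integer rank")
  r <- as.integer(r)
  m <- nrow(V); n <- ncol(V)
  set.seed(seed)
  W0 <- matrix(runif(m * r), m, r)
  H0 <- matrix(runif(r * n), r, n)
  fit <- nmf_engine(V, W0, H0, as.integer(max_iter), tol,
                    as.integer(window), eps)
  W <- fit$W; H <- fit$H
  rownames(W) <- rownames(V)
  dec <- new_decomposition(W, H, R2 = fit$R2, iterations = fit$iterations,
                           seed = as.integer(seed), r2_trace = fit$r2_trace)
  dec
}

#' Best factorization over random restarts
#'
#' Repeats [nmf_factorize()] with fresh random initial matrices
#' (seeds `base_seed`, `base_seed + 1`, ...) to avoid local minima and
#' returns the decomposition with the highest reconstruction R^2.
#'
#' @param V As in [nmf_factorize()].
#' @param r Factorization rank.
#' @param n_restarts Number of restarts (default 10).
#' @param base_seed Seed of the first restart.
#' @param ... Passed on to [nmf_factorize()].
#' @return The best `decomposition` across restarts.
#' @export
best_of_restarts <- function(V, r, n_restarts = 10, base_seed = 1L, ...) {
  if (n_restarts < 1) stop("`n_restarts` must be at least 1")
  best <- NULL
  for (s in base_seed + seq_len(n_restarts) - 1L) {
    dec <- nmf_factorize(V, r, seed = s, ...)
    if (is.null(best) || dec$R2 > best$R2) best <- dec
  }
  best
}

#' Choose the factorization rank from the R^2-versus-rank curve
#'
#' Fits a simple linear regression to the R^2-versus-rank curve and
#' computes the mean squared error of the residuals. If the MSE is below
#' `mse_threshold` the curve is deemed linear and the first rank on it is
#' chosen; otherwise the lowest-rank point is dropped and the fit repeated,
#' until the MSE criterion is met or only two points remain. This selects
#' the start of the most linear part of the curve, where adding synergies
#' no longer improves reconstruction appreciably.
#'
#' @param r2_by_rank Numeric vector of best-of-restarts R^2 values for
#'   ranks `1:length(r2_by_rank)` (normally 9 values).
#' @param mse_threshold Linearity threshold on the residual MSE
#'   (default 1e-4).
#' @return A list with `chosen_rank` and `trace` (a `rank_selection_trace`
#'   with `r2_by_rank`, `mse_path`, `chosen_rank`).
#' @export
select_rank <- function(r2_by_rank, mse_threshold = 1e-4) {
  r2_by_rank <- as.numeric(r2_by_rank)
  if (length(r2_by_rank) < 2) stop("need at least two R^2 values")
  ranks <- seq_along(r2_by_rank)
  cur <- ranks
  mse_path <- numeric(0)
  repeat {
    fit <- lm.fit(cbind(1, cur), r2_by_rank[cur])
    mse <- mean(fit$residuals^2)
    mse_path <- c(mse_path, mse)
    if (mse < mse_threshold || length(cur) <= 2) break
    cur <- cur[-1]
  }
  chosen <- cur[1]
  trace <- structure(list(r2_by_rank = r2_by_rank, mse_path = mse_path,
                          chosen_rank = chosen),
                     class = "rank_selection_trace")
  list(chosen_rank = chosen, trace = trace)
}

#' @export
print.rank_selection_trace <- function(x, ...) {
  cat(sprintf("<rank_selection_trace> chosen rank %d after %d linear fits\n",
              x$chosen_rank, length(x$mse_path)))
  invisible(x)
}

#' Extract muscle synergies with automatic rank selection
#'
#' Runs [best_of_restarts()] for every candidate rank (1 to `max_rank`,
#' default 9 -- the rounded 75% of the 12 recorded muscles, so that
#' factorization always reduces dimensionality), builds the
#' R^2-versus-rank curve from the best restart at each rank, applies
#' [select_rank()], and returns the stored best decomposition at the chosen
#' rank.
#'
#' Restart seeds are `base_seed + (rank-1)*n_restarts + 0:(n_restarts-1)`,
#' so every factorization in the sweep has a distinct, reproducible seed.
#'
#' @param V A `normalized_emg` or nonnegative matrix.
#' @param base_seed Base seed for the restart sweep.
#' @param max_rank Highest candidate rank (default 9).
#' @param n_restarts Restarts per rank (default 10).
#' @param mse_threshold Rank-selection linearity threshold (default 1e-4).
#' @param ... Passed on to [nmf_factorize()] (`max_iter`, `tol`, ...).
#' @return A list with `decomposition` (best at the chosen rank) and
#'   `trace` (the `rank_selection_trace`).
#' @export
extract_synergies <- function(V, base_seed = 1L, max_rank = 9,
                              n_restarts = 10, mse_threshold = 1e-4, ...) {
  V <- .as_V(V)
  best_by_rank <- vector("list", max_rank)
  for (r in seq_len(max_rank)) {
    best_by_rank[[r]] <- best_of_restarts(
      V, r, n_restarts = n_restarts,
      base_seed = base_seed + (r - 1L) * n_restarts, ...)
  }
  r2s <- vapply(best_by_rank, `[[`, numeric(1), "R2")
  sel <- select_rank(r2s, mse_threshold = mse_threshold)
  list(decomposition = best_by_rank[[sel$chosen_rank]], trace = sel$trace)
}
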