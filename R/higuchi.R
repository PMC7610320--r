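#' Higuchi curve length at one time interval
#'
#' For a series H(1), ..., H(n) and an integer interval k, builds the k
#' decimated subseries starting at offsets t0 = 1..k, computes each
#' non-Euclidean curve length
#' L_t0(k) = (1/k) * (n-1) / (floor((n-t0)/k) * k) * sum |H(t0+ik) - H(t0+(i-1)k)|,
#' and returns their average L(k). For a fractal curve L(k) scales as
#' k^(-HFD).
#'
#' @param series Numeric vector, length n > k.
#' @param k Integer interval, 1 <= k < n.
#' @return The average curve length L(k).
#' @export
higuchi_curve_length <- function(series, k) {
  series <- as.numeric(series)
  n <- length(series)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  if (k >= n) stop("`k` must be smaller than the series length")
  Lt <- numeric(k)
  for (t0 in seq_len(k)) {
    m <- (n - t0) %/% k
    if (m < 1) { Lt[t0] <- 0; next }
    idx <- t0 + (0:m) * k
    Lt[t0] <- (1 / k) * sum(abs(diff(series[idx]))) * (n - 1) / (m * k)
  }
  mean(Lt)
}

#' Higuchi fractal dimension of a time series
#'
#' Estimates local complexity from the scaling of curve length with the
#' sampling interval. The series is first min-subtracted and normalized to
#' its maximum (which leaves the slope, and hence the estimate, unchanged:
#' the log L(k) vs log(1/k) line changes intercept but not slope under
#' amplitude scaling). L(k) is computed for k = k_min..kmax and the HFD is
#' the ordinary-least-squares slope of log L(k) on log(1/k), using natural
#' logarithms. Values range from 1 for a smooth linear series to about 2
#' for random white noise.
#'
#' @param series Non-constant numeric vector; lengths below `10 * kmax`
#'   give a warning (few points per decimated subseries).
#' @param kmax Largest interval (default 10, the most linear region of the
#'   log-log plot for 6000-point locomotor primitives).
#' @param k_min Smallest interval (default 1, the canonical full range;
#'   raise to reproduce stricter readings of the interval constraint).
#' @return An object of class `higuchi_fd`: `hfd` (the slope), `fit_r2`
#'   (goodness of the log-log fit), `loglog` (data frame with `log_inv_k`,
#'   `log_L`), `kmax`, `k_min`.
#' @export
higuchi_fd <- function(series, kmax = 10, k_min = 1) {
  series <- as.numeric(series)
  if (kmax < 2 || k_min < 1 || k_min >= kmax)
    stop("need 1 <= k_min < kmax and kmax >= 2")
  rng <- range(series)
  if (rng[2] - rng[1] <= 0) stop("zero-length curve: series is constant")
  if (length(series) < 10 * kmax)
    warning("series shorter than 10 * kmax; HFD estimate may be unstable")
  x <- (series - rng[1]) / (rng[2] - rng[1])
  ks <- k_min:kmax
  L <- vapply(ks, function(k) higuchi_curve_length(x, k), numeric(1))
  if (any(L == 0)) {
    if (all(L == 0)) stop("zero-length curve")
    stop("curve length L(k) vanished for some k but not all; HFD undefined")
  }
  lx <- log(1 / ks)
  ly <- log(L)
  fit <- lm.fit(cbind(1, lx), ly)
  slope <- unname(fit$coefficients[2])
  fit_r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  structure(list(hfd = slope, fit_r2 = fit_r2,
                 loglog = data.frame(log_inv_k = lx, log_L = ly),
                 kmax = kmax, k_min = k_min),
            class = "higuchi_fd")
}

#' @export
print.higuchi_fd <- function(x, ...) {
  cat(sprintf("<higuchi_fd> HFD = %.4f (log-log fit R2 = %.5f, k = %d..%d)\n",
              x$hfd, x$fit_r2, x$k_min, x$kmax))
  invisible(x)
}

#' Trial-level Higuchi fractal dimension of motor primitives
#'
#' Computes the HFD of each motor primitive separately over its full
#' concatenated length (200 points x cycles) and averages, so every trial
#' yields one HFD value. Combined synergies are included (unlike the FWHM
#' analysis). Degenerate (constant) primitives are excluded from the mean
#' with a warning.
#'
#' @param H A `decomposition` or an r x n primitives matrix (one row per
#'   synergy).
#' @param kmax,k_min Passed to [higuchi_fd()].
#' @return An `hfd_result`: `per_primitive_hfd`, `trial_hfd` (their mean),
#'   `fit_r2`, `kmax`.
#' @export
trial_hfd <- function(H, kmax = 10, k_min = 1) {
  if (inherits(H, "decomposition")) H <- H$H
  H <- as.matrix(H)
  if (nrow(H) < 1) stop("need at least one primitive")
  vals <- rep(NA_real_, nrow(H))
  r2s <- rep(NA_real_, nrow(H))
  for (i in seq_len(nrow(H))) {
    if (diff(range(H[i, ])) <= 0) {
      warning("primitive ", i, " is constant; excluded from the trial HFD")
      next
    }
    f <- higuchi_fd(H[i, ], kmax = kmax, k_min = k_min)
    vals[i] <- f$hfd
    r2s[i] <- f$fit_r2
  }
  if (all(is.na(vals))) stop("all primitives degenerate; trial HFD undefined")
  structure(list(per_primitive_hfd = vals,
                 trial_hfd = mean(vals, na.rm = TRUE),
                 fit_r2 = r2s, kmax = kmax),
            class = "hfd_result")
}

#' @export
print.hfd_result <- function(x, ...) {
  cat(sprintf("<hfd_result> trial HFD = %.4f over %d primitives (kmax = %d)\n",
              x$trial_hfd, length(x$per_primitive_hfd), x$kmax))
  invisible(x)
}
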