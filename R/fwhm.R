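#' Full width at half maximum of one gait cycle
#'
#' After subtracting the cycle's minimum, counts the number of normalized
#' time points at or above half the cycle's maximum. With the default
#' `"ge"` convention the peak sample itself always counts; `"gt"` counts
#' only points strictly exceeding the half maximum (the two differ by at
#' most a couple of points on smooth primitives).
#'
#' @param cycle Numeric vector, one time-normalized gait cycle
#'   (conventionally 200 points).
#' @param convention `"ge"` (at or above half maximum, default) or `"gt"`
#'   (strictly above).
#' @return Integer width in time points, or `NA` (with a warning) for a
#'   constant cycle, where the half maximum is undefined.
#' @export
fwhm_cycle <- function(cycle, convention = c("ge", "gt")) {
  convention <- match.arg(convention)
  cycle <- as.numeric(cycle)
  x <- cycle - min(cycle)
  peak <- max(x)
  if (peak <= 0) {
    warning("constant cycle: FWHM undefined")
    return(NA_integer_)
  }
  half <- peak / 2
  if (convention == "ge") sum(x >= half) else sum(x > half)
}

#' Mean full width at half maximum of a motor primitive
#'
#' Splits a concatenated primitive into consecutive cycles, computes
#' [fwhm_cycle()] for each and averages, ignoring undefined (constant)
#' cycles. This duration metric is meaningful only for fundamental
#' synergies (single main activation peak); callers exclude
#' combined-labelled primitives upstream.
#'
#' @param primitive Numeric vector of length `points_per_cycle * cycles`.
#' @param points_per_cycle Points per gait cycle (default 200).
#' @param convention Passed to [fwhm_cycle()].
#' @return An `fwhm_result`: `per_cycle_width` (integer vector, `NA` for
#'   undefined cycles) and `mean_width`.
#' @export
fwhm_primitive <- function(primitive, points_per_cycle = 200,
                           convention = c("ge", "gt")) {
  convention <- match.arg(convention)
  primitive <- as.numeric(primitive)
  n <- length(primitive)
  if (n %% points_per_cycle != 0)
    stop("primitive length is not a multiple of `points_per_cycle`")
  n_cycles <- n %/% points_per_cycle
  widths <- vapply(seq_len(n_cycles), function(i) {
    seg <- primitive[(i - 1L) * points_per_cycle + seq_len(points_per_cycle)]
    suppressWarnings(fwhm_cycle(seg, convention))
  }, integer(1))
  if (all(is.na(widths)))
    stop("FWHM undefined for every cycle (constant primitive)")
  if (anyNA(widths))
    warning(sum(is.na(widths)), " constant cycle(s) excluded from the FWHM mean")
  structure(list(per_cycle_width = widths,
                 mean_width = mean(widths, na.rm = TRUE)),
            class = "fwhm_result")
}

#' @export
print.fwhm_result <- function(x, ...) {
  cat(sprintf("<fwhm_result> mean width %.1f points over %d cycles\n",
              x$mean_width, length(x$per_cycle_width)))
  invisible(x)
}
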