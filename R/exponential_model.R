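# Exponential modeling of the sorted voxel-intensity distribution of the
# summed-pyruvate image inside the endocardial ROI.
#
# Sorted descending, the N masked intensities I1 >= ... >= IN are modeled
# as I_j = Imax * exp(-B * (j - 1)), a single-parameter description of how
# concentrated (large B) or diffuse (small B) the blood-pool signal is.

#' Sorted intensity profile of the endocardial summed-pyruvate signal
#'
#' Extracts all masked voxel values and sorts them in descending order.
#' Ties keep the stable grid (column-major raster) order of extraction; the
#' fitted decay constant is invariant to the order of tied values.
#'
#' @param sum_pyr summed-pyruvate image matrix.
#' @param endo logical endocardial mask, non-empty, same shape.
#' @return An `intensity_profile`: list with descending `values`, count
#'   `n`, `i_max = values[1]`, `i_min = values[n]`.
#' @export
sort_roi <- function(sum_pyr, endo) {
  stopifnot(is.matrix(sum_pyr), identical(dim(sum_pyr), dim(endo)))
  if (!any(endo)) stopf("endocardial mask is empty")
  vals <- sum_pyr[as.vector(endo)]
  vals <- vals[order(-vals)]  # stable: ties keep raster order
  structure(list(values = vals, n = length(vals),
                 i_max = vals[1L], i_min = vals[length(vals)]),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> N = %d, Imax = %.4g, Imin = %.4g\n",
              x$n, x$i_max, x$i_min))
  invisible(x)
}

#' Fit the exponential rank-decay model to a sorted intensity profile
#'
#' The amplitude is fixed at the observed maximum (`I1 = Imax` by
#' construction), leaving the decay constant B as the single free
#' parameter. B is estimated by least squares in the log domain with the
#' intercept pinned at `log(I1)`:
#' `B = sum_j (j-1) * log(I1 / I_j) / sum_j (j-1)^2`.
#' Values are floored at `max(Imin, 1e-12 * Imax)` (with a pure
#' `1e-12 * Imax` floor when Imin is non-positive) before taking logs.
#' The coefficient of determination is reported on the linear scale
#' between the fitted curve and the sorted data, the scale on which fit
#' quality is conventionally quoted for these profiles. An optional
#' nonlinear refinement minimizes the linear-scale sum of squares over B
#' with Imax still fixed.
#'
#' @param profile an `intensity_profile` with `n >= 3` and `i_max > 0`.
#' @param refine logical; golden-section refinement of B on the linear
#'   scale (default FALSE).
#' @return An `exp_fit`: list with `b_value`, `i_max`, `i_min`, `n`, `r2`.
#'   A constant profile gives `b_value = 0`, `r2 = 1`.
#' @examples
#' p <- structure(list(values = 1286 * exp(-0.0105 * (0:227)), n = 228,
#'                     i_max = 1286, i_min = 1286 * exp(-0.0105 * 227)),
#'                class = "intensity_profile")
#' fit_exponential(p)$b_value  # 0.0105
#' @export
fit_exponential <- function(profile, refine = FALSE) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (profile$n < 3L) stopf("need at least 3 voxels to fit; got %d", profile$n)
  if (!is.finite(profile$i_max) || profile$i_max <= 0)
    stopf("nonpositive maximum intensity (%s); cannot fit", format(profile$i_max))
  v <- profile$values
  eps <- max(profile$i_min, 1e-12 * profile$i_max)
  if (eps <= 0) eps <- 1e-12 * profile$i_max
  v <- pmax(v, eps)
  j <- seq_along(v) - 1
  b <- sum(j * (log(v[1L]) - log(v))) / sum(j * j)
  b <- max(b, 0)
  if (refine && b > 0) {
    sse <- function(bb) sum((profile$values - profile$i_max * exp(-bb * j))^2)
    b <- stats::optimize(sse, c(b / 4, b * 4))$minimum
  }
  fitted <- profile$i_max * exp(-b * j)
  sst <- sum((profile$values - mean(profile$values))^2)
  r2 <- if (sst > 0) 1 - sum((profile$values - fitted)^2) / sst else 1
  structure(list(b_value = b, i_max = profile$i_max, i_min = profile$i_min,
                 n = profile$n, r2 = r2),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> B = %.4g, Imax = %.4g, N = %d, R2 = %.3f\n",
              x$b_value, x$i_max, x$n, x$r2))
  invisible(x)
}

#' Closed-form retained-voxel count for an ideal exponential profile
#'
#' Independent oracle for threshold selection: on a profile that is exactly
#' `Imax * exp(-B * (j - 1))`, the number of values at or above the
#' adaptive threshold `(alpha/100) * Imax + Imin` is
#' `1 + floor(log(Imax / threshold) / B)`, clipped to `[1, n]`; a
#' threshold above Imax retains the single maximal voxel (the comparison
#' used throughout is inclusive).
#'
#' @param i_max,i_min profile extremes, `i_max > 0`, `0 <= i_min <= i_max`.
#' @param b decay constant, > 0.
#' @param alpha threshold percentage in (0, 100].
#' @param n profile length; defaults to the ideal-profile value
#'   `round(1 + log(i_max / i_min) / b)`.
#' @return Integer retained count.
#' @export
retained_count_oracle <- function(i_max, i_min, b, alpha, n = NULL) {
  stopifnot(is_scalar_num(b), b > 0, is_scalar_num(alpha),
            alpha > 0, alpha <= 100, i_max > 0, i_min >= 0, i_min <= i_max)
  if (is.null(n)) {
    if (i_min <= 0) stopf("n must be given when i_min is 0")
    n <- round(1 + log(i_max / i_min) / b)
  }
  thr <- alpha / 100 * i_max + i_min
  if (thr > i_max) return(1L)
  as.integer(min(max(1, 1 + floor(log(i_max / thr) / b)), n))
}
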