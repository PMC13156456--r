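# The three LV pyruvate delivery models and the per-study normalized
# metrics:
#   numerical-fitting model  B / Pyr(alpha%)   (proposed)
#   peak-intensity model     Imax / Pyr(alpha%)
#   percentile model         B / Pyr(T%)       (traditional baseline)
# where Pyr(.) is the area under the mean-SNR time curve of the retained
# voxels. Alpha is expressed in percent everywhere: the adaptive threshold
# is (alpha/100) * Imax + Imin.

#' Study-specific maximum usable threshold percentage
#'
#' The largest alpha at which the adaptive threshold still equals the
#' maximal observed intensity, i.e. only the brightest voxel(s) survive:
#' `alpha_max = (Imax - Imin) / Imax * 100`.
#'
#' @param i_max maximum masked intensity, > 0.
#' @param i_min minimum masked intensity, in `[0, i_max]`.
#' @return Percentage in `[0, 100]`.
#' @examples
#' alpha_max(1286, 94.9)  # 92.62
#' @export
alpha_max <- function(i_max, i_min) {
  if (!is_scalar_num(i_max) || i_max <= 0)
    stopf("i_max must be positive; got %s", format(i_max))
  stopifnot(is_scalar_num(i_min), i_min <= i_max)
  (i_max - i_min) / i_max * 100
}

#' Cohort-wide upper limit of the integer threshold grid
#'
#' The threshold sweep uses integer alpha from 1 up to the largest value
#' usable by every study: the floor of the cohort minimum of the per-study
#' `alpha_max` values. A cohort whose minimum alpha_max is just below 64
#' yields the grid 1..63.
#'
#' @param alpha_maxes numeric vector of per-study `alpha_max` values.
#' @return Integer upper limit.
#' @export
alpha_grid_upper <- function(alpha_maxes) {
  stopifnot(length(alpha_maxes) >= 1L, all(is.finite(alpha_maxes)))
  m <- min(alpha_maxes)
  if (m < 1) stopf("cohort minimum alpha_max (%s) below 1%%: no usable grid",
                   format(m))
  as.integer(floor(m))
}

#' Select the adaptive-threshold blood-pool ROI
#'
#' Retains the endocardial voxels whose summed-pyruvate value is at or
#' above `(alpha/100) * Imax + Imin`. The comparison is inclusive so that
#' at `alpha = alpha_max` exactly the maximal voxel(s) survive (a strict
#' comparison would retain nothing there); voxels tied at the threshold are
#' all retained. If no voxel survives (degenerate all-equal profile, where
#' the threshold exceeds Imax), the maximal voxel(s) are retained with a
#' warning.
#'
#' @param sum_pyr summed-pyruvate image matrix.
#' @param endo logical endocardial mask.
#' @param alpha threshold percentage, > 0.
#' @param profile optional `intensity_profile` for `sum_pyr` within `endo`
#'   (computed if missing).
#' @return A `threshold_selection`: list with `alpha`, `threshold_value`,
#'   logical `retained_mask`, `n_retained`, and `pyr_alpha` (NA until
#'   [pyr_alpha_curve()] is applied).
#' @export
select_threshold <- function(sum_pyr, endo, alpha, profile = NULL) {
  if (is.null(profile)) profile <- sort_roi(sum_pyr, endo)
  stopifnot(inherits(profile, "intensity_profile"),
            is_scalar_num(alpha), alpha > 0)
  thr <- alpha / 100 * profile$i_max + profile$i_min
  retained <- endo & (sum_pyr >= thr)
  if (!any(retained)) {
    warning("no voxel at or above the threshold; retaining the maximal voxel(s)",
            call. = FALSE)
    retained <- endo & (sum_pyr >= profile$i_max)
  }
  structure(list(alpha = alpha, threshold_value = thr,
                 retained_mask = retained, n_retained = sum(retained),
                 pyr_alpha = NA_real_),
            class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat(sprintf("<threshold_selection> alpha = %g%%, threshold = %.4g, %d voxels%s\n",
              x$alpha, x$threshold_value, x$n_retained,
              if (is.na(x$pyr_alpha)) "" else sprintf(", Pyr = %.4g", x$pyr_alpha)))
  invisible(x)
}

#' Mean-SNR time curve and Pyr(alpha%) over a thresholded ROI
#'
#' Averages the voxel-wise SNR of the pyruvate series over the retained
#' voxels at every frame; the trapezoidal area under that curve is the
#' delivery term Pyr(alpha%).
#'
#' @param pyr flip-angle corrected pyruvate `dynamic_series`.
#' @param selection a `threshold_selection` from the same study.
#' @param noise a `noise_estimate`.
#' @return The selection with `pyr_alpha` filled in and the `snr_curve`
#'   attached as `$curve`.
#' @export
pyr_alpha_curve <- function(pyr, selection, noise) {
  stopifnot(inherits(selection, "threshold_selection"))
  cv <- snr_curve(pyr, selection$retained_mask, noise)
  selection$curve <- cv
  selection$pyr_alpha <- cv$auc
  selection
}

#' Percentile (top-T%) delivery model Pyr(T%)
#'
#' Retains the `ceiling(T/100 * N)` highest-intensity endocardial voxels
#' (at least one; ties at the cut broken by stable raster order, so exactly
#' that many voxels are kept) and returns the mean-SNR AUC over them.
#'
#' @param pyr flip-angle corrected pyruvate `dynamic_series`.
#' @param sum_pyr summed-pyruvate image matrix.
#' @param endo logical endocardial mask.
#' @param T_pct percentile in `[1, 100]`.
#' @param noise a `noise_estimate`.
#' @param profile optional precomputed `intensity_profile`.
#' @return List with `T_pct`, `n_retained`, `retained_mask`, `pyr_T`
#'   (the AUC) and the `snr_curve` as `$curve`.
#' @export
percentile_model <- function(pyr, sum_pyr, endo, T_pct, noise, profile = NULL) {
  stopifnot(is_scalar_num(T_pct), T_pct >= 1, T_pct <= 100)
  if (is.null(profile)) profile <- sort_roi(sum_pyr, endo)
  k <- max(1L, as.integer(ceiling(T_pct / 100 * profile$n)))
  idx <- which(as.vector(endo))
  top <- idx[order(-sum_pyr[idx])[seq_len(k)]]
  retained <- matrix(FALSE, nrow(sum_pyr), ncol(sum_pyr))
  retained[top] <- TRUE
  cv <- snr_curve(pyr, retained, noise)
  list(T_pct = T_pct, n_retained = k, retained_mask = retained,
       pyr_T = cv$auc, curve = cv)
}

#' Assemble the per-study normalized delivery metrics
#'
#' Combines the exponential fit, the threshold and percentile delivery
#' terms, and the metabolic outcome into one record:
#' `metric_numfit(alpha) = B / Pyr(alpha%)`,
#' `metric_peak(alpha) = Imax / Pyr(alpha%)`,
#' `metric_percentile(T) = B / Pyr(T%)`.
#' A zero delivery term makes the corresponding metric NA (flagged with a
#' warning) rather than infinite.
#'
#' @param fit an `exp_fit`.
#' @param pyr_alpha named numeric vector of Pyr(alpha%) over the alpha grid.
#' @param pyr_T named numeric vector of Pyr(T%) over the T grid.
#' @param n_retained_alpha,n_retained_T integer vectors of retained counts.
#' @param lac_bic scalar metabolic outcome.
#' @return A `study_metrics` object (list).
#' @export
study_metrics <- function(fit, pyr_alpha, pyr_T, n_retained_alpha = NULL,
                          n_retained_T = NULL, lac_bic = NA_real_) {
  stopifnot(inherits(fit, "exp_fit"))
  safe_div <- function(num, den, label) {
    bad <- !is.na(den) & den == 0
    if (any(bad)) {
      warning(sprintf("%s undefined at %d grid point(s) with zero delivery term",
                      label, sum(bad)), call. = FALSE)
      den[bad] <- NA_real_
    }
    num / den
  }
  structure(list(
    b_value = fit$b_value, i_max = fit$i_max, i_min = fit$i_min,
    n = fit$n, r2 = fit$r2,
    pyr_alpha = pyr_alpha, pyr_T = pyr_T,
    n_retained_alpha = n_retained_alpha, n_retained_T = n_retained_T,
    metric_numfit = safe_div(fit$b_value, pyr_alpha, "B/Pyr(alpha)"),
    metric_peak = safe_div(fit$i_max, pyr_alpha, "Imax/Pyr(alpha)"),
    metric_percentile = safe_div(fit$b_value, pyr_T, "B/Pyr(T)"),
    lac_bic = lac_bic), class = "study_metrics")
}
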