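# Cohort-level statistics: the threshold sweep correlating each delivery
# metric with the metabolic outcome, regime detection, and the
# model-comparison tests (paired t over thresholds, Fisher Z at a chosen
# threshold, correlation-vs-voxel-count trend, Cohen's d).

#' Pearson correlation coefficient
#'
#' `Cov(X, Y) / (SD_X * SD_Y)` with the sample (n-1) convention used
#' consistently in numerator and denominator. Errors on constant input,
#' where the coefficient is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' pearson(1:4, c(2, 1, 4, 3))  # 0.6
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3L) stopf("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stopf("missing values in correlation input")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stopf("correlation undefined for a constant vector")
  stats::cov(x, y) / (sx * sy)
}

#' Relative change between two correlation values, in percent
#'
#' `|r2 - r1| / |r1| * 100`; used to express how sensitive a model's
#' cohort correlation is to moving between two thresholds.
#'
#' @param r1,r2 correlation values, `r1 != 0`.
#' @return Percentage.
#' @export
relative_correlation_change <- function(r1, r2) {
  stopifnot(is_scalar_num(r1), is_scalar_num(r2), r1 != 0)
  abs(r2 - r1) / abs(r1) * 100
}

#' Sweep a delivery metric across the threshold grid
#'
#' For every grid point (alpha or T), computes the cohort Pearson
#' correlation between the metric and the metabolic outcome, locates the
#' most negative correlation (the optimum: lower LV pyruvate delivery
#' metrics associate with higher lactate+bicarbonate, so correlations are
#' negative and the sweep minimizes, never maximizes the absolute value),
#' and labels regimes:
#' \describe{
#'   \item{optimal}{the contiguous window around the argmin where
#'     `corr <= min(corr) + delta`;}
#'   \item{noise}{points left of the window on the decreasing approach
#'     (low thresholds still diluted by low-SNR voxels);}
#'   \item{plateau}{points right of the window where successive changes
#'     stay within `delta`;}
#'   \item{transition}{anything else.}
#' }
#' Studies with an undefined (NA) metric at a grid point are dropped from
#' that point's correlation with a message.
#'
#' @param metric matrix `studies x grid` of metric values.
#' @param outcome numeric vector of per-study metabolic outcomes.
#' @param grid numeric grid labels (default column count sequence).
#' @param delta window/plateau tolerance on the correlation scale;
#'   default 0.005.
#' @return A `sweep_result`: list with `grid`, `corr`, `argmin_alpha`,
#'   `optimal_window` (grid value range), `regime_labels`, `n_used`.
#' @export
sweep_metric <- function(metric, outcome, grid = NULL, delta = 0.005) {
  metric <- as.matrix(metric)
  if (nrow(metric) < 4L) stopf("need at least 4 studies; got %d", nrow(metric))
  if (ncol(metric) < 1L) stopf("empty grid")
  if (length(outcome) != nrow(metric))
    stopf("outcome length %d does not match %d studies",
          length(outcome), nrow(metric))
  if (is.null(grid)) grid <- seq_len(ncol(metric))
  stopifnot(length(grid) == ncol(metric), is_scalar_num(delta), delta >= 0)

  corr <- numeric(ncol(metric))
  n_used <- integer(ncol(metric))
  dropped <- 0L
  for (k in seq_len(ncol(metric))) {
    ok <- is.finite(metric[, k]) & is.finite(outcome)
    dropped <- dropped + sum(!ok)
    if (sum(ok) < 3L) stopf("fewer than 3 usable studies at grid point %s",
                            format(grid[k]))
    corr[k] <- pearson(metric[ok, k], outcome[ok])
    n_used[k] <- sum(ok)
  }
  if (dropped > 0L)
    message(sprintf("sweep: dropped %d study/grid-point pairs with undefined metrics",
                    dropped))

  i_min <- which.min(corr)
  in_win <- corr <= corr[i_min] + delta
  # contiguous window containing the argmin
  lo <- i_min; hi <- i_min
  while (lo > 1L && in_win[lo - 1L]) lo <- lo - 1L
  while (hi < length(corr) && in_win[hi + 1L]) hi <- hi + 1L

  labels <- rep("transition", length(corr))
  labels[lo:hi] <- "optimal"
  if (lo > 1L) {
    k <- lo - 1L
    while (k >= 1L && corr[k] > corr[k + 1L]) {  # still descending into window
      labels[k] <- "noise"
      k <- k - 1L
    }
  }
  if (hi < length(corr)) {
    k <- hi + 1L
    while (k <= length(corr) && abs(corr[k] - corr[k - 1L]) <= delta) {
      labels[k] <- "plateau"
      k <- k + 1L
    }
  }

  structure(list(grid = grid, corr = corr,
                 argmin_alpha = grid[i_min],
                 optimal_window = c(grid[lo], grid[hi]),
                 regime_labels = labels, n_used = n_used, delta = delta),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d grid points; min corr %.3f at %g; window [%g, %g]\n",
              length(x$grid), min(x$corr), x$argmin_alpha,
              x$optimal_window[1L], x$optimal_window[2L]))
  invisible(x)
}

#' Compare two threshold sweeps
#'
#' Paired two-tailed t-test over the per-threshold correlation pairs of
#' two sweeps on the same grid, plus a Fisher Z test for the difference of
#' the two correlations at one chosen threshold, using `z = atanh(r)` and
#' standard error `sqrt(2 / (n - 3))` for two correlations estimated on
#' the same `n` studies.
#'
#' @param sweep_a,sweep_b `sweep_result` objects on identical grids.
#' @param n_studies number of studies behind each correlation.
#' @param alpha_test grid value at which to run the Fisher Z test.
#' @return A `comparison_stats` list: `paired_t` (statistic, df, p),
#'   `fisher_z` (z, p, r_a, r_b, alpha), and `mean_sd` per sweep.
#' @export
compare_models <- function(sweep_a, sweep_b, n_studies, alpha_test) {
  stopifnot(inherits(sweep_a, "sweep_result"), inherits(sweep_b, "sweep_result"))
  if (!isTRUE(all.equal(sweep_a$grid, sweep_b$grid)))
    stopf("sweeps are on different grids")
  stopifnot(is_count(n_studies, min = 4L))
  d <- sweep_a$corr - sweep_b$corr
  n <- length(d)
  df <- n - 1L
  sd_d <- stats::sd(d)
  tstat <- if (sd_d == 0) 0 else mean(d) / (sd_d / sqrt(n))
  p_t <- if (sd_d == 0) 1 else 2 * stats::pt(-abs(tstat), df)

  k <- which(sweep_a$grid == alpha_test)
  if (length(k) != 1L) stopf("alpha_test = %s not on the sweep grid",
                             format(alpha_test))
  ra <- sweep_a$corr[k]; rb <- sweep_b$corr[k]
  z <- (atanh(ra) - atanh(rb)) / sqrt(2 / (n_studies - 3))
  p_z <- 2 * stats::pnorm(-abs(z))

  structure(list(
    paired_t = list(statistic = tstat, df = df, p_value = p_t),
    fisher_z = list(statistic = z, p_value = p_z, r_a = ra, r_b = rb,
                    alpha = alpha_test),
    mean_sd = list(a = c(mean = mean(sweep_a$corr), sd = stats::sd(sweep_a$corr)),
                   b = c(mean = mean(sweep_b$corr), sd = stats::sd(sweep_b$corr)))),
    class = "comparison_stats")
}

#' Correlation-versus-voxel-count trend of a sweep
#'
#' How strongly a model's cohort correlation depends on how many voxels
#' its ROI retains: Spearman rank correlation (average ranks on ties) and
#' the ordinary least-squares slope and R-squared of correlation against
#' the mean retained voxel count per grid point.
#'
#' @param sweep a `sweep_result`.
#' @param mean_counts mean retained voxel count per grid point (positive).
#' @return List with `spearman_rho`, `slope`, `r2`.
#' @export
voxel_count_trend <- function(sweep, mean_counts) {
  stopifnot(inherits(sweep, "sweep_result"),
            length(mean_counts) == length(sweep$corr))
  if (any(mean_counts <= 0)) stopf("voxel counts must be positive")
  rho <- stats::cor(mean_counts, sweep$corr, method = "spearman")
  fit <- stats::lm(sweep$corr ~ mean_counts)
  list(spearman_rho = rho,
       slope = unname(stats::coef(fit)[2L]),
       r2 = summary(fit)$r.squared)
}

#' Cohen's d effect size
#'
#' Difference of group means over the pooled standard deviation with the
#' `(n_a + n_b - 2)` denominator.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return Scalar effect size.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stopf("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stopf("zero pooled standard deviation; effect size undefined")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}
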