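# Adaptive threshold, percentile model, and the normalized metrics.

# plant a sorted vector of values into a row of a grid, masked
planted_image <- function(values, grid = 24L) {
  img <- matrix(0, grid, grid)
  mask <- matrix(FALSE, grid, grid)
  stopifnot(length(values) <= grid * grid)
  idx <- seq_along(values)
  img[idx] <- values
  mask[idx] <- TRUE
  list(img = img, mask = mask)
}

test_that("alpha_max evaluates its defining formula", {
  expect_equal(alpha_max(1286, 94.9), (1286 - 94.9) / 1286 * 100)
  expect_equal(alpha_max(1286, 94.9), 92.62, tolerance = 1e-3)
  expect_equal(alpha_max(5, 5), 0)
  expect_equal(alpha_max(5, 0), 100)
  expect_error(alpha_max(0, 0), "positive")
})

test_that("alpha grid upper limit floors the cohort minimum", {
  expect_identical(alpha_grid_upper(c(92.6, 63.7, 88.1)), 63L)
  expect_identical(alpha_grid_upper(92.6), 92L)
  expect_error(alpha_grid_upper(c(50, 0.5)), "below 1")
})

test_that("threshold selection is inclusive and handles the boundary", {
  p <- exp_profile(0.0180, 200)
  pi200 <- planted_image(p$values)
  # oracle equivalence at the pinned example
  sel <- select_threshold(pi200$img, pi200$mask, 20)
  expect_identical(sel$n_retained, 83L)
  # alpha = alpha_max retains only the argmax voxel
  am <- alpha_max(p$i_max, p$i_min)
  sel_max <- select_threshold(pi200$img, pi200$mask, am)
  expect_identical(sel_max$n_retained, 1L)
  expect_true(pi200$img[sel_max$retained_mask] == p$i_max)
  # any alpha > 0 excludes the minimum voxel on a spread profile
  sel1 <- select_threshold(pi200$img, pi200$mask, 0.5)
  expect_lt(sel1$n_retained, p$n)
  # all-equal profile: fallback retains the maximal voxels with a warning
  flat <- planted_image(rep(4, 30))
  expect_warning(self <- select_threshold(flat$img, flat$mask, 10),
                 "maximal")
  expect_identical(self$n_retained, 30L)
})

test_that("oracle equivalence holds exhaustively on exact profiles", {
  set.seed(31)
  for (i in 1:10) {
    b <- runif(1, 0.004, 0.019)
    n <- sample(c(151, 228, 315), 1)
    imax <- runif(1, 126, 5577)
    p <- exp_profile(b, n, imax)
    pim <- planted_image(p$values, grid = 20L)
    for (a in 1:63)
      expect_identical(select_threshold(pim$img, pim$mask, a, p)$n_retained,
                       as.integer(retained_count_oracle(p$i_max, p$i_min,
                                                        b, a, n)))
  }
})

test_that("percentile model keeps ceil(T/100 * N) voxels, min one", {
  p <- exp_profile(0.01, 229, 1000)
  pim <- planted_image(p$values)
  series <- dynamic_series(array(rep(as.vector(pim$img), each = 4),
                                 c(4, 24, 24)),
                           5, corrected = TRUE)
  nz <- unit_noise(1)
  m10 <- percentile_model(series, pim$img, pim$mask, 10, nz)
  expect_identical(m10$n_retained, 23L)          # ceil(22.9)
  m100 <- percentile_model(series, pim$img, pim$mask, 100, nz)
  expect_identical(m100$n_retained, 229L)
  expect_equal(m100$pyr_T, snr_curve(series, pim$mask, nz)$auc)
  # Pyr(T) nonincreasing in T on any profile
  set.seed(32)
  for (rep in 1:5) {
    vals <- sort(abs(rnorm(80, 100, 60)), decreasing = TRUE)
    pim2 <- planted_image(vals, grid = 12L)
    s2 <- dynamic_series(array(rep(as.vector(pim2$img), each = 3),
                               c(3, 12, 12)), 5, corrected = TRUE)
    aucs <- sapply(seq(5, 100, by = 5), function(Tp)
      percentile_model(s2, pim2$img, pim2$mask, Tp, nz)$pyr_T)
    expect_true(all(diff(aucs) <= 1e-12))
  }
})

test_that("pyr_alpha_curve reduces to the single voxel trace", {
  p <- exp_profile(0.02, 50, 500)
  pim <- planted_image(p$values, grid = 10L)
  trace <- c(0, 3, 9, 4, 1)
  arr <- array(rep(as.vector(pim$img), each = 5), c(5, 10, 10)) *
    rep(trace / sum(trace), times = 100)
  series <- dynamic_series(arr, 5, corrected = TRUE)
  sel <- select_threshold(pim$img, pim$mask, alpha_max(p$i_max, p$i_min))
  expect_identical(sel$n_retained, 1L)
  out <- pyr_alpha_curve(series, sel, unit_noise(2))
  expect_equal(out$curve$values, p$i_max * trace / sum(trace) / 2)
  expect_equal(out$pyr_alpha, out$curve$auc)
})

test_that("study metrics divide correctly and flag zero delivery", {
  f <- fit_exponential(exp_profile(0.0105, 228, 1286))
  pa <- c(`1` = 200, `13` = 300, `20` = 320)
  pt <- c(`10` = 500, `100` = 190)
  m <- study_metrics(f, pa, pt, lac_bic = 44)
  expect_equal(m$metric_numfit, f$b_value / pa)
  expect_equal(m$metric_peak, f$i_max / pa)
  expect_equal(m$metric_percentile, f$b_value / pt)
  # zero decay constant gives a zero metric
  f0 <- fit_exponential(profile_from_values(rep(2, 10)))
  expect_true(all(study_metrics(f0, pa, pt)$metric_numfit == 0))
  w <- capture_warnings(mz <- study_metrics(f, c(`1` = 0), pt))
  expect_match(w, "zero delivery", all = TRUE)
  expect_true(is.na(mz$metric_numfit[["1"]]))
  expect_true(is.na(mz$metric_peak[["1"]]))
})

test_that("metric scale behavior: numfit invariant, peak tracks Imax/sigma", {
  st <- make_study(small_spec(101))
  m1 <- compute_study_metrics(st, alpha_grid = c(5, 20), T_grid = 50)
  st2 <- st
  for (met in c("pyruvate", "lactate", "bicarbonate"))
    st2[[met]]$frames <- st[[met]]$frames * 2   # doubles signal AND noise
  m2 <- compute_study_metrics(st2, alpha_grid = c(5, 20), T_grid = 50)
  # SNR-based delivery is invariant, so B/Pyr is invariant; Imax doubles,
  # so the peak metric doubles
  expect_equal(m2$metric_numfit, m1$metric_numfit, tolerance = 1e-6)
  expect_equal(m2$metric_peak, 2 * m1$metric_peak, tolerance = 1e-6)
})

test_that("peak metric exceeds one on a concentrated phantom", {
  st <- make_study(small_spec(102, planted_B = 0.0180))
  m <- compute_study_metrics(st, alpha_grid = 20, T_grid = 50)
  expect_gt(m$metric_peak[["20"]], 1)
})
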