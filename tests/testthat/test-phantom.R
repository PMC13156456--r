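# Phantom generator: planted-structure contracts, determinism, and the
# cohort outcome planting.

test_that("noiseless phantoms carry an exactly exponential profile", {
  sp <- phantom_spec(noise_sigma = 0, profile_jitter = 0, seed = 3)
  st <- make_study(sp)
  pyr <- flip_angle_correct(st$pyruvate)
  prof <- sort_roi(sum_pyruvate(pyr), st$masks$endo)
  n <- st$truth$n_endo
  expect_equal(prof$values, 1286 * exp(-0.0105 * (seq_len(n) - 1)),
               tolerance = 1e-10)
  f <- fit_exponential(prof)
  expect_lt(abs(f$b_value - 0.0105) / 0.0105, 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-9)
})

test_that("brighter voxels sit nearer the LV center (radial ordering)", {
  sp <- small_spec(4, noise_sigma = 0, profile_jitter = 0)
  st <- make_study(sp)
  sp_img <- sum_pyruvate(flip_angle_correct(st$pyruvate))
  idx <- which(st$masks$endo)
  g <- sp$grid_size
  d2 <- ((idx - 1) %% g - sp$lv_center[1])^2 +
    ((idx - 1) %/% g - sp$lv_center[2])^2
  # the brightest voxel sits at the minimal radius, and intensity is
  # nonincreasing along the center-out (radius, then angle) ordering
  vals <- sp_img[idx]
  expect_equal(d2[which.max(vals)], min(d2))
  ang <- atan2((idx - 1) %/% g - sp$lv_center[2],
               (idx - 1) %% g - sp$lv_center[1])
  o <- order(d2, ang)
  expect_true(all(diff(vals[o]) <= 1e-9))
  # quartile check: top-quartile voxels lie well inside the bottom quartile
  qs <- quantile(vals, c(0.25, 0.75))
  expect_lt(mean(d2[vals >= qs[2]]), mean(d2[vals <= qs[1]]))
})

test_that("baseline frames are noise-only and the bolus peaks on schedule", {
  sp <- small_spec(5)
  st <- make_study(sp)
  b <- sp$bolus
  w <- gamma_variate(1:44, b[["t0"]], b[["k"]], b[["beta"]], b[["amplitude"]])
  # pre-onset pyruvate frames: zero mean up to noise
  pre <- st$pyruvate$frames[1:b[["t0"]], , ]
  expect_lt(abs(mean(pre)), 4 * sp$noise_sigma / sqrt(length(pre)))
  # mean in-ROI signal peaks at the gamma-variate argmax
  roi_mean <- sapply(1:44, function(f) mean(st$pyruvate$frames[f, , ][st$masks$endo]))
  expect_equal(which.max(roi_mean), which.max(w))
  # metabolite baseline (excitation suspended) frames are noise-only
  met_base <- st$lactate$frames[seq_len(sp$baseline_frames / 2), , ]
  expect_lt(abs(mean(met_base)), 4 * sp$noise_sigma / sqrt(length(met_base)))
  # metabolite signal sits in the myocardial band, not the blood pool
  lac_sum <- sum_pyruvate(flip_angle_correct(st$lactate))
  expect_gt(mean(lac_sum[st$masks$myo]), 10 * mean(abs(lac_sum[st$masks$endo])))
})

test_that("equal seeds are bit-identical; different seeds differ", {
  a <- make_study(small_spec(7))
  b <- make_study(small_spec(7))
  expect_identical(a$pyruvate$frames, b$pyruvate$frames)
  expect_identical(a$lactate$frames, b$lactate$frames)
  c <- make_study(small_spec(8))
  expect_false(identical(a$pyruvate$frames, c$pyruvate$frames))
  # generation does not disturb the caller's RNG stream
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(make_study(small_spec(9))); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("three planted decay regimes give steep/moderate/shallow profiles", {
  ms <- lapply(c(0.0180, 0.0105, 0.0028), function(b)
    compute_study_metrics(make_study(small_spec(10, planted_B = b)),
                          alpha_grid = 20, T_grid = 50))
  bs <- sapply(ms, `[[`, "b_value")
  expect_true(all(diff(bs) < 0))           # recovered in the right order
  # concentrated signal retains fewer voxels at a fixed threshold
  frac <- sapply(ms, function(m) m$n_retained_alpha[["20"]] / m$n)
  expect_true(all(diff(frac) > 0))
})

test_that("phantom spec validation rejects bad geometry and parameters", {
  expect_error(phantom_spec(grid_size = 15), "grid_size")
  expect_error(phantom_spec(n_pyr_frames = 40, n_met_frames = 22), "2 \\*")
  expect_error(phantom_spec(planted_B = 0), "positive")
  expect_error(phantom_spec(endo_radii = c(60, 60)), "outside")
  expect_error(phantom_spec(grid_size = 20, endo_radii = c(9, 9)), "outside")
})

test_that("cohort planting hits the target correlation and validates input", {
  expect_error(make_cohort(4, rho_target = 0.5), "negative")
  expect_error(make_cohort(4, rho_target = 0), "negative")
  expect_error(make_cohort(3), "is_count")

  # minimum cohort size runs end-to-end
  co4 <- make_cohort(4, seed = 11, grid_size = 32, alpha_grid = c(1, 13),
                     T_grid = c(10, 100), keep_studies = FALSE)
  expect_length(co4$metrics, 4)
  expect_equal(nrow(co4$truth), 4)

  # planted association: realized correlation at alpha* near the target,
  # averaged over replicate cohorts (scaled-down Monte-Carlo; the
  # acceptance suite runs the full-size version)
  rs <- sapply(1:8, function(r) {
    co <- make_cohort(40, seed = 100 + r, grid_size = 32,
                      alpha_grid = 13, T_grid = 10, keep_studies = FALSE)
    pearson(metrics_matrix(co, "numfit")[, "13"], co$outcome$lac_bic)
  })
  expect_lt(abs(mean(rs) - (-0.6)), 0.1)

  # zero coupling slope: metric and outcome uncorrelated
  co0 <- make_cohort(40, seed = 12, grid_size = 32, alpha_grid = 13,
                     T_grid = 10, keep_studies = FALSE,
                     rho_target = -1e-6)
  r0 <- pearson(metrics_matrix(co0, "numfit")[, "13"], co0$outcome$lac_bic)
  expect_lt(abs(r0), 2.5 / sqrt(40))

  # truth table carries the planted parameters within their stated ranges
  expect_true(all(co4$truth$planted_B >= 0.0028 & co4$truth$planted_B <= 0.0183))
  expect_true(all(co4$truth$planted_Imax >= 126 & co4$truth$planted_Imax <= 5577))
  expect_true(all(co4$truth$n_endo >= 100))
})
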