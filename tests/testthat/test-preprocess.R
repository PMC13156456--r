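# Grid interpolation, flip-angle correction, noise, SNR curves, SUMPyr.

test_that("k-space zero-fill preserves DC and mean-square energy", {
  s <- dynamic_series(array(3.5, c(2, 44, 43)), flip_angle = 5)
  out <- to_analysis_grid(s, 100)
  expect_equal(dim(out$frames), c(2, 100, 100))
  # constant over the embedded region; border ringing from the zero pad
  # stays away from the grid interior
  expect_equal(mean(out$frames[1, 20:80, 20:80]), 3.5, tolerance = 0.05)

  set.seed(3)
  img <- matrix(rnorm(44 * 44), 44, 44)
  s2 <- dynamic_series(array(rep(img, each = 2), c(2, 44, 44)), flip_angle = 5)
  out2 <- to_analysis_grid(s2, 100)
  # Parseval: energy density (mean square) is conserved by the zero-fill
  expect_equal(mean(out2$frames[1, , ]^2), mean(img^2), tolerance = 1e-6)
})

test_that("orientation operations behave as rigid ops", {
  img <- matrix(1:12, 3, 4)
  expect_identical(hplvpool:::orient_image(hplvpool:::orient_image(img, flip_h = TRUE), flip_h = TRUE),
                   img)  # involution
  expect_identical(hplvpool:::orient_image(hplvpool:::orient_image(img, flip_v = TRUE), flip_v = TRUE),
                   img)
  expect_identical(hplvpool:::orient_image(img, rotations = 4), img)
  expect_identical(hplvpool:::orient_image(hplvpool:::orient_image(img, 1), 3), img)
})

test_that("flip-angle correction divides by sin(theta) exactly once", {
  arr <- array(1, c(2, 4, 4))
  expect_equal(flip_angle_correct(dynamic_series(arr, 30))$frames,
               arr * 2)
  expect_equal(flip_angle_correct(dynamic_series(arr, 90))$frames, arr)
  expect_equal(flip_angle_correct(dynamic_series(arr, 5))$frames,
               arr / sin(5 * pi / 180), tolerance = 1e-12)
  expect_equal(flip_angle_correct(dynamic_series(arr, 5))$frames[1, 1, 1],
               11.4737, tolerance = 1e-4)
  expect_error(flip_angle_correct(flip_angle_correct(dynamic_series(arr, 30))),
               "already")
})

test_that("noise estimation recovers sigma and ignores offsets", {
  set.seed(11)
  arr <- array(rnorm(30 * 50 * 50, sd = 2), c(30, 50, 50))
  s <- dynamic_series(arr, 5, corrected = TRUE)
  est <- estimate_noise(s, 1:30)
  expect_lt(abs(est$sigma - 2) / 2, 0.05)
  # per-frame offsets do not change the estimate
  s_off <- s
  s_off$frames <- s$frames + rep(seq(100, 390, by = 10), times = 50 * 50)
  expect_equal(estimate_noise(s_off, 1:30)$sigma, est$sigma, tolerance = 1e-12)
  # single-voxel region reduces to the sample SD of the centered trace
  reg <- matrix(FALSE, 50, 50); reg[7, 9] <- TRUE
  expect_equal(estimate_noise(s, 1:30, reg)$sigma, sd(arr[, 7, 9]))
  expect_error(estimate_noise(s, 1L), "at least 2")
  expect_error(estimate_noise(dynamic_series(array(1, c(4, 3, 3)), 5), 1:4),
               "zero variance")
})

test_that("SNR curves and AUCs match closed forms and quadrature", {
  mask <- matrix(TRUE, 8, 8)
  s <- toy_series(rep(3, 10), base = 3)
  cv <- snr_curve(s, mask, unit_noise(1))
  expect_equal(cv$values, rep(3, 10))
  expect_equal(cv$auc, 3 * 9)                    # constant: s * (F - 1)
  tri <- c(0:5, 4:0)                             # triangle 0..p..0, k = 5
  cv2 <- snr_curve(toy_series(tri, base = tri), mask, unit_noise(1))
  expect_equal(cv2$auc, 5 * 5)                   # p * k

  # gamma-variate bolus sampled per frame vs numerical quadrature of the
  # same piecewise-linear interpolant (what the trapezoid integrates)
  tt <- 1:44
  g <- gamma_variate(tt, 8, 3, 2.5)
  cv3 <- snr_curve(toy_series(g, base = g), mask, unit_noise(1))
  quad <- integrate(approxfun(tt, g), 1, 44, subdivisions = 2000L)$value
  expect_equal(cv3$auc, quad, tolerance = 2e-2)
})

test_that("SUMPyr is a linear voxel-wise frame sum", {
  z <- dynamic_series(array(0, c(3, 5, 5)), 5)
  expect_true(all(sum_pyruvate(z) == 0))
  one <- array(0, c(3, 5, 5)); one[2, , ] <- matrix(1:25, 5, 5)
  expect_equal(sum_pyruvate(dynamic_series(one, 5)), matrix(1:25, 5, 5))
  set.seed(5)
  x <- dynamic_series(array(rnorm(75), c(3, 5, 5)), 5)
  y <- dynamic_series(array(rnorm(75), c(3, 5, 5)), 5)
  mix <- x; mix$frames <- 2 * x$frames + 3 * y$frames
  expect_equal(sum_pyruvate(mix), 2 * sum_pyruvate(x) + 3 * sum_pyruvate(y))
})

test_that("metabolic outcome is additive in the two metabolite AUCs", {
  mask <- matrix(TRUE, 8, 8)
  set.seed(6)
  a <- array(abs(rnorm(4 * 64)), c(4, 8, 8))
  b <- array(abs(rnorm(4 * 64)), c(4, 8, 8))
  lac <- dynamic_series(a, 30, "lactate", 2L, corrected = TRUE)
  bic <- dynamic_series(b, 30, "bicarbonate", 2L, corrected = TRUE)
  nz <- unit_noise(2)
  out <- metabolic_outcome(lac, bic, mask, nz)
  expect_equal(out, snr_curve(lac, mask, nz)$auc + snr_curve(bic, mask, nz)$auc)
  zero <- dynamic_series(array(0, c(4, 8, 8)), 30, corrected = TRUE)
  expect_equal(metabolic_outcome(zero, zero, mask, nz), 0)
  expect_equal(metabolic_outcome(lac, zero, mask, nz),
               snr_curve(lac, mask, nz)$auc)
  # equals the AUC of the summed curve (linearity of the trapezoid)
  both <- lac; both$frames <- a + b
  expect_equal(out, snr_curve(both, mask, nz)$auc)
  expect_error(metabolic_outcome(lac, bic, matrix(FALSE, 8, 8), nz), "empty")
})

test_that("SNR AUC is invariant to jointly rescaling signal and sigma", {
  mask <- matrix(TRUE, 8, 8)
  set.seed(7)
  v <- abs(rnorm(10))
  s <- toy_series(v, base = v)
  a1 <- snr_curve(s, mask, unit_noise(1.3))$auc
  s2 <- s; s2$frames <- s$frames / sin(30 * pi / 180)
  a2 <- snr_curve(s2, mask, unit_noise(1.3 / sin(30 * pi / 180)))$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  # full-grid curve equals the mean of per-voxel curves
  per_voxel <- sapply(1:8, function(i) sapply(1:8, function(j) {
    m <- matrix(FALSE, 8, 8); m[i, j] <- TRUE
    snr_curve(s, m, unit_noise(1.3))$values
  }))
  expect_equal(snr_curve(s, mask, unit_noise(1.3))$values,
               rowMeans(matrix(per_voxel, nrow = 10)))
})
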