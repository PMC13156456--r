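# Preprocessing of dynamic 13C image series: analysis-grid interpolation,
# flip-angle correction, baseline noise estimation, SNR time curves and
# their areas under the curve, and the summed-pyruvate image.

#' Dynamic metabolite image series
#'
#' Container for one metabolite's 2D+time stack. Frames are stored as a 3D
#' array indexed `[frame, row, col]` in arbitrary units. Pyruvate is
#' acquired every heartbeat over 44 frames with a 5 degree excitation;
#' lactate and bicarbonate are reconstructed every two heartbeats over 22
#' frames with a 30 degree excitation.
#'
#' @param frames numeric 3D array `[frame, row, col]` with at least 2
#'   frames.
#' @param flip_angle excitation flip angle in degrees, in (0, 90].
#' @param metabolite label, e.g. "pyruvate", "lactate", "bicarbonate".
#' @param frame_interval heartbeats per frame (1 pyruvate, 2 metabolites).
#' @param corrected logical; whether flip-angle correction has been applied.
#' @return A `dynamic_series` object.
#' @export
dynamic_series <- function(frames, flip_angle, metabolite = "pyruvate",
                           frame_interval = 1L, corrected = FALSE) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stopf("frames must be a 3D array [frame, row, col]")
  if (dim(frames)[1L] < 2L) stopf("a dynamic series needs at least 2 frames")
  if (!is_scalar_num(flip_angle) || flip_angle <= 0 || flip_angle > 90)
    stopf("flip_angle must lie in (0, 90] degrees; got %s", format(flip_angle))
  stopifnot(is_count(frame_interval))
  structure(list(frames = frames, flip_angle = flip_angle,
                 metabolite = metabolite,
                 frame_interval = as.integer(frame_interval),
                 corrected = isTRUE(corrected)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dynamic_series> %s: %d frames of %dx%d, flip %g deg%s\n",
              x$metabolite, d[1L], d[2L], d[3L], x$flip_angle,
              if (x$corrected) " (flip-corrected)" else ""))
  invisible(x)
}

n_frames <- function(series) dim(series$frames)[1L]

# Frames as an F x V matrix (voxels in column-major grid order), the
# layout every per-voxel operation works on.
frames_matrix <- function(series) {
  d <- dim(series$frames)
  matrix(series$frames, nrow = d[1L], ncol = d[2L] * d[3L])
}

#' Interpolate a raw series to the square analysis grid
#'
#' Raw reconstructions arrive on a small (possibly non-square, e.g. 44 x 43
#' from half-scan acquisition) matrix. Each frame is zero-padded to square,
#' Fourier transformed, symmetrically zero-filled in k-space to
#' `target x target` (sinc interpolation, the standard MR zero-fill), and
#' inverse transformed; the magnitude image is scaled so the DC level (image
#' mean) is preserved exactly, which also preserves the mean-square energy
#' density. The stated rigid orientation operations (90-degree rotations
#' then horizontal/vertical flips) are applied identically to all frames.
#' An image-domain bilinear fallback is available via `method`.
#'
#' @param series a `dynamic_series` on a grid smaller than `target`.
#' @param target output side; default 100.
#' @param rotations number of 90-degree counter-clockwise rotations (0-3).
#' @param flip_h,flip_v logical, horizontal (column) / vertical (row) flips
#'   applied after rotation.
#' @param method "kspace" (default) or "bilinear".
#' @return A `dynamic_series` with `target x target` frames.
#' @export
to_analysis_grid <- function(series, target = 100L, rotations = 0L,
                             flip_h = FALSE, flip_v = FALSE,
                             method = c("kspace", "bilinear")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "dynamic_series"), is_count(target))
  d <- dim(series$frames)
  if (max(d[2L], d[3L]) > target)
    stopf("raw grid %dx%d is not smaller than target %d", d[2L], d[3L], target)
  fr <- d[1L]
  out <- array(0, c(fr, target, target))
  for (f in seq_len(fr)) {
    img <- series$frames[f, , ]
    img <- if (method == "kspace") kspace_zerofill(img, target)
           else bilinear_resize(img, target)
    img <- orient_image(img, rotations, flip_h, flip_v)
    out[f, , ] <- img
  }
  s <- series
  s$frames <- out
  s
}

# Zero-fill interpolation of one frame: pad to square, centered FFT,
# embed into the target spectrum, inverse FFT, magnitude. Scaling
# target_tot/n_tot keeps a constant image constant (DC preservation) and
# the mean square of the image unchanged (Parseval with the padded
# spectrum untouched).
kspace_zerofill <- function(img, target) {
  n <- max(dim(img))
  sq <- matrix(0, n, n)
  sq[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  spec <- fftshift2(stats::fft(sq))
  big <- matrix(0+0i, target, target)
  off <- floor((target - n) / 2)
  big[off + seq_len(n), off + seq_len(n)] <- spec
  rec <- stats::fft(ifftshift2(big), inverse = TRUE) / (target * target)
  Mod(rec) * (target * target) / (n * n)
}

fftshift2 <- function(m) {
  r <- nrow(m); c <- ncol(m)
  m[c((floor(r / 2) + 1):r, seq_len(floor(r / 2))),
    c((floor(c / 2) + 1):c, seq_len(floor(c / 2)))]
}

ifftshift2 <- function(m) {
  r <- nrow(m); c <- ncol(m)
  m[c((r - floor(r / 2) + 1):r, seq_len(r - floor(r / 2))),
    c((c - floor(c / 2) + 1):c, seq_len(c - floor(c / 2)))]
}

bilinear_resize <- function(img, target) {
  nr <- nrow(img); nc <- ncol(img)
  # map output voxel centers onto input pixel-center coordinates
  rx <- (seq_len(target) - 0.5) * nr / target - 0.5
  cx <- (seq_len(target) - 0.5) * nc / target - 0.5
  r0 <- pmin(pmax(floor(rx), 0), nr - 1); r1 <- pmin(r0 + 1, nr - 1)
  c0 <- pmin(pmax(floor(cx), 0), nc - 1); c1 <- pmin(c0 + 1, nc - 1)
  wr <- rx - r0; wc <- cx - c0
  a <- img[r0 + 1, c0 + 1, drop = FALSE] * outer(1 - wr, 1 - wc)
  b <- img[r0 + 1, c1 + 1, drop = FALSE] * outer(1 - wr, wc)
  cc <- img[r1 + 1, c0 + 1, drop = FALSE] * outer(wr, 1 - wc)
  d <- img[r1 + 1, c1 + 1, drop = FALSE] * outer(wr, wc)
  a + b + cc + d
}

# k x 90-degree counter-clockwise rotation then optional flips.
orient_image <- function(img, rotations = 0L, flip_h = FALSE, flip_v = FALSE) {
  k <- ((rotations %% 4) + 4) %% 4
  for (i in seq_len(k)) img <- t(img)[rev(seq_len(ncol(img))), , drop = FALSE]
  if (flip_h) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  if (flip_v) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  img
}

#' Flip-angle correction
#'
#' Divides every voxel of every frame by `sin(theta)` of the excitation
#' flip angle (5 degrees for pyruvate gives a factor ~11.47; 30 degrees for
#' lactate/bicarbonate gives exactly 2), normalizing excitation efficiency
#' across metabolites. Correcting twice is an error.
#'
#' @param series a `dynamic_series`.
#' @return The corrected series with `corrected = TRUE`.
#' @export
flip_angle_correct <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  if (series$corrected)
    stopf("series '%s' is already flip-angle corrected", series$metabolite)
  s <- series
  s$frames <- series$frames / sin(series$flip_angle * pi / 180)
  s$corrected <- TRUE
  s
}

#' Estimate the noise standard deviation from baseline frames
#'
#' Baseline frames (acquired before any metabolite excitation, or before
#' bolus arrival) contain noise only. Sigma is the standard deviation of
#' all (voxel, frame) samples in `region` across `baseline_frames`, after
#' subtracting each frame's region mean so that a constant offset does not
#' inflate the estimate.
#'
#' @param series a `dynamic_series`.
#' @param baseline_frames integer indices of noise-only frames (at least 2).
#' @param region logical mask matrix (default: whole grid).
#' @return A `noise_estimate`: list with `sigma`, `source_frames`,
#'   `source_region`.
#' @export
estimate_noise <- function(series, baseline_frames, region = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$frames)
  if (is.null(region)) region <- matrix(TRUE, d[2L], d[3L])
  if (!any(region)) stopf("noise region is empty")
  if (length(baseline_frames) < 2L)
    stopf("need at least 2 baseline frames; got %d", length(baseline_frames))
  if (any(baseline_frames < 1L) || any(baseline_frames > d[1L]))
    stopf("baseline frame index out of range 1..%d", d[1L])
  m <- frames_matrix(series)[baseline_frames, as.vector(region), drop = FALSE]
  if (ncol(m) >= 2L) {
    # remove each frame's region mean (offset-robust), then pool with the
    # proper per-frame degrees of freedom F * (V - 1)
    centered <- m - rowMeans(m)
    sigma <- sqrt(sum(centered^2) / (nrow(m) * (ncol(m) - 1L)))
  } else {
    # single-voxel region: per-frame offsets are not identifiable; use the
    # sample SD of the trace over the baseline frames
    sigma <- stats::sd(m)
  }
  if (!is.finite(sigma) || sigma <= 0)
    stopf("baseline samples have zero variance; cannot estimate noise")
  structure(list(sigma = sigma, source_frames = as.integer(baseline_frames),
                 source_region = region),
            class = "noise_estimate")
}

#' Mean SNR time curve over a mask, with its area under the curve
#'
#' Voxel-wise SNR (value divided by `noise$sigma`) is averaged over the
#' mask at every frame; the area under the resulting curve is computed by
#' the trapezoidal rule at unit frame spacing.
#'
#' @param series a flip-angle corrected `dynamic_series`.
#' @param mask logical mask matrix, non-empty.
#' @param noise a `noise_estimate`.
#' @return An `snr_curve`: list with per-frame `values` and scalar `auc`.
#' @export
snr_curve <- function(series, mask, noise) {
  stopifnot(inherits(series, "dynamic_series"),
            inherits(noise, "noise_estimate"))
  if (!any(mask)) stopf("SNR mask is empty")
  m <- frames_matrix(series)[, as.vector(mask), drop = FALSE]
  values <- rowMeans(m) / noise$sigma
  structure(list(values = values, auc = trapz_unit(values)),
            class = "snr_curve")
}

#' Summed-pyruvate image
#'
#' Voxel-wise sum of all dynamic pyruvate frames; the static map on which
#' the rank-intensity distribution is modeled and thresholds are applied.
#'
#' @param series a `dynamic_series`.
#' @return Numeric matrix of the per-voxel frame sums.
#' @export
sum_pyruvate <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$frames)
  matrix(colSums(frames_matrix(series)), d[2L], d[3L])
}

#' Metabolic outcome: lactate + bicarbonate SNR AUC in the mid-myocardium
#'
#' The downstream metabolic outcome is the sum of the mean-SNR areas under
#' the curve of the lactate and bicarbonate series over the mid-myocardial
#' mask.
#'
#' @param lac,bic flip-angle corrected `dynamic_series` with equal frame
#'   counts.
#' @param mid_myo logical mask, non-empty.
#' @param noise a `noise_estimate` shared by both series.
#' @return Scalar Lac+Bic value (SNR x frame units).
#' @export
metabolic_outcome <- function(lac, bic, mid_myo, noise) {
  if (!any(mid_myo)) stopf("mid-myocardial mask is empty")
  if (n_frames(lac) != n_frames(bic))
    stopf("lactate (%d) and bicarbonate (%d) frame counts differ",
          n_frames(lac), n_frames(bic))
  snr_curve(lac, mid_myo, noise)$auc + snr_curve(bic, mid_myo, noise)$auc
}
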