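# Parametric LV region-of-interest geometry on the square analysis grid.
#
# The epicardial contour is an ellipse supplied as parameters (center,
# semi-axes, rotation). The endocardial contour is the same ellipse with both
# semi-axes shrunk by a fixed factor, the myocardium is the band between
# them, and the mid-myocardial band erodes both boundaries of that band
# toward its mid-line to exclude partial-volume voxels.

#' Construct the LV mask set from a parametric epicardial ellipse
#'
#' Membership is decided at voxel centers using 0-based `(row, col)`
#' coordinates: voxel `(i, j)` is inside an ellipse with center
#' `(r0, c0)`, semi-axes `(a, b)` (row, col) and rotation `angle` when
#' `(u/a)^2 + (v/b)^2 <= 1` for the rotated offsets `(u, v)`. There are no
#' partial voxels, so every mask is reproducible by brute-force point
#' counting.
#'
#' The endocardial ellipse shares the center and angle with the epicardial
#' one, with both semi-axes multiplied by `endo_scale`. The myocardium is
#' `epic & !endo`. The mid-myocardial band shrinks both bounding ellipses
#' toward the band mid-line by `mid_myo_shrink` of the band half-width
#' (default 10%).
#'
#' @param center numeric length-2, ellipse center `(row, col)` in 0-based
#'   voxel coordinates.
#' @param semi_axes numeric length-2, epicardial semi-axes `(a, b)` in
#'   voxels (row, col direction before rotation).
#' @param angle rotation of the ellipse in degrees (counter-clockwise in
#'   `(row, col)` space); default 0.
#' @param endo_scale fraction in (0, 1) applied to both semi-axes to obtain
#'   the endocardial ellipse; default 0.8. The factor is a configuration
#'   choice: the source protocol reduces the radius but does not print the
#'   factor.
#' @param mid_myo_shrink fraction in `[0, 0.5)` of the myocardial band
#'   half-width by which each boundary is moved toward the band mid-line;
#'   default 0.10.
#' @param grid_size side of the square analysis grid in voxels; default 100.
#' @return A `mask_set` object: list with logical `grid_size x grid_size`
#'   matrices `epic`, `endo`, `myo`, `mid_myo` plus `grid_size`.
#'   Invariants: `endo` is a subset of `epic`, `myo = epic & !endo`,
#'   `mid_myo` is a subset of `myo`, all non-empty.
#' @examples
#' m <- build_masks(c(50, 50), c(20, 20), endo_scale = 0.8)
#' sum(m$endo)   # ~ pi * 16^2 voxel centers
#' @export
build_masks <- function(center, semi_axes, angle = 0, endo_scale = 0.8,
                        mid_myo_shrink = 0.10, grid_size = 100L) {
  stopifnot(length(center) == 2L, length(semi_axes) == 2L,
            is_scalar_num(angle), is_count(grid_size, min = 4L))
  if (!is_scalar_num(endo_scale) || endo_scale <= 0 || endo_scale >= 1)
    stopf("endo_scale must lie strictly in (0, 1); got %s", format(endo_scale))
  if (!is_scalar_num(mid_myo_shrink) || mid_myo_shrink < 0 || mid_myo_shrink >= 0.5)
    stopf("mid_myo_shrink must lie in [0, 0.5); got %s", format(mid_myo_shrink))
  if (any(semi_axes <= 0)) stopf("semi-axes must be positive")

  epic <- ellipse_mask(center, semi_axes, angle, grid_size)
  if (!any(epic)) stopf("epicardial ellipse interior is empty on the grid")
  endo <- ellipse_mask(center, semi_axes * endo_scale, angle, grid_size)
  if (!any(endo))
    stopf("endocardial mask empty after scaling by endo_scale = %s",
          format(endo_scale))
  myo <- epic & !endo
  if (!any(myo))
    stopf("myocardial band empty: endo_scale = %s leaves no band voxels",
          format(endo_scale))

  # Erode the band from both boundaries toward its mid-line. The band
  # half-width along each semi-axis is a*(1 - s)/2; move each bounding
  # ellipse in by mid_myo_shrink of that half-width.
  h <- semi_axes * (1 - endo_scale) / 2
  outer_ax <- semi_axes - mid_myo_shrink * h
  inner_ax <- semi_axes * endo_scale + mid_myo_shrink * h
  mid_myo <- ellipse_mask(center, outer_ax, angle, grid_size) &
    !ellipse_mask(center, inner_ax, angle, grid_size)
  if (!any(mid_myo))
    stopf("mid-myocardial band empty after %s boundary shrink",
          format(mid_myo_shrink))

  structure(list(epic = epic, endo = endo, myo = myo, mid_myo = mid_myo,
                 grid_size = as.integer(grid_size)),
            class = "mask_set")
}

# Voxel-center point-in-ellipse membership on a 0-based grid.
ellipse_mask <- function(center, semi_axes, angle, grid_size) {
  idx <- seq_len(grid_size) - 1L
  rows <- matrix(idx, grid_size, grid_size) - center[1L]
  cols <- matrix(idx, grid_size, grid_size, byrow = TRUE) - center[2L]
  th <- angle * pi / 180
  u <- cos(th) * rows + sin(th) * cols
  v <- -sin(th) * rows + cos(th) * cols
  (u / semi_axes[1L])^2 + (v / semi_axes[2L])^2 <= 1
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %dx%d grid: epic %d, endo %d, myo %d, mid_myo %d voxels\n",
              x$grid_size, x$grid_size, sum(x$epic), sum(x$endo),
              sum(x$myo), sum(x$mid_myo)))
  invisible(x)
}

#' Downsample a high-resolution square reference image to the analysis grid
#'
#' Area-weighted block averaging: output voxel `(i, j)` averages the input
#' over the rectangle it covers in the original field of view, with exact
#' fractional-pixel weights, so the field of view and the image mean are
#' preserved exactly (to floating point) for any integer or non-integer
#' ratio (e.g. 432 -> 100).
#'
#' @param image square numeric matrix, side at least `target`.
#' @param target output side length; default 100.
#' @return `target x target` numeric matrix with the same mean intensity.
#' @examples
#' x <- matrix(7, 432, 432)
#' all(downsample_reference(x) == 7)
#' @export
downsample_reference <- function(image, target = 100L) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stopf("input must be a square matrix; got %dx%d",
          NROW(image), NCOL(image))
  stopifnot(is_count(target, min = 1L))
  n <- nrow(image)
  if (n < target) stopf("input side %d smaller than target %d", n, target)
  w <- block_weights(n, target)
  w %*% image %*% t(w)
}

# target x n aggregation matrix; row i holds the overlap of input pixel
# [j-1, j) with output cell [i*r, (i+1)*r), r = n/target, normalized by r.
# Rows sum to 1 (mean-preserving) and columns sum to 1/r (mass-consistent).
block_weights <- function(n, target) {
  r <- n / target
  w <- matrix(0, target, n)
  for (i in seq_len(target)) {
    lo <- (i - 1) * r
    hi <- i * r
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) w[i, j] <- ov / r
    }
  }
  w
}
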