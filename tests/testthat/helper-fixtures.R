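# Shared fixtures, built in code.

# exact exponential intensity profile
exp_profile <- function(b, n, i_max = 1) {
  v <- i_max * exp(-b * (seq_len(n) - 1))
  structure(list(values = v, n = n, i_max = v[1L], i_min = v[n]),
            class = "intensity_profile")
}

profile_from_values <- function(v) {
  v <- sort(v, decreasing = TRUE)
  structure(list(values = v, n = length(v), i_max = v[1L],
                 i_min = v[length(v)]),
            class = "intensity_profile")
}

# tiny dynamic series: one bright voxel trace on an otherwise flat grid
toy_series <- function(values_by_frame, grid = 8L, flip = 90,
                       base = 0, corrected = TRUE) {
  f <- length(values_by_frame)
  arr <- array(base, c(f, grid, grid))
  arr[, 3L, 4L] <- values_by_frame
  dynamic_series(arr, flip_angle = flip, metabolite = "pyruvate",
                 corrected = corrected)
}

unit_noise <- function(sigma = 1) {
  structure(list(sigma = sigma, source_frames = 1:2,
                 source_region = matrix(TRUE, 1, 1)),
            class = "noise_estimate")
}

# small, fast phantom with the natural ROI size
small_spec <- function(seed, grid = 32L, ...) {
  phantom_spec(grid_size = grid, seed = seed, ...)
}
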