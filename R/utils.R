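# Internal helpers shared across modules.

#' Trapezoidal area under a curve sampled at unit spacing
#'
#' @param y numeric vector of samples.
#' @return Scalar area; for a constant value s over F frames this is
#'   `s * (F - 1)`.
#' @keywords internal
#' @noRd
trapz_unit <- function(y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum(y) - (y[1L] + y[n]) / 2
}

# Evaluate a function with a temporary RNG state seeded at `seed`,
# restoring the caller's .Random.seed afterwards so library calls do not
# perturb user-level reproducibility.
with_local_seed <- function(seed, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  fun()
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
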