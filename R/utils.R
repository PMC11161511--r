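# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global random-number state so that package
#' functions with a `seed` argument are deterministic without clobbering
#' the caller's stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-index sub-seed (32-bit safe) so that per-trial random
# draws do not shift when trials are appended.
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 69621) %% 2147483629)
}

#' Gaussian smoothing of a uniformly binned series
#'
#' Convolves with a truncated (4 SD) Gaussian kernel; edges are
#' renormalized by the kernel mass actually inside the series, so a
#' constant input is returned unchanged.
#'
#' @param x numeric vector.
#' @param sd_bins kernel standard deviation in bins; `<= 0` returns `x`.
#' @return Smoothed numeric vector, same length as `x`.
#' @export
gauss_smooth <- function(x, sd_bins) {
  stopifnot(is.numeric(x))
  if (length(x) == 0L || sd_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_bins))
  k <- dnorm(seq.int(-half, half), sd = sd_bins)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  num <- convolve(xp, k, type = "open")
  den <- convolve(wp, k, type = "open")
  idx <- (2L * half + 1L):(2L * half + n)
  num[idx] / den[idx]
}

# Sort, round to `resolution` seconds and drop duplicate event times.
canonical_times <- function(times, resolution = 1e-4) {
  times <- sort(times)
  times <- round(times / resolution) * resolution
  unique(times)
}

# First index of sorted `x` that is >= each element of `at` (0 if none).
first_at_or_after <- function(x, at) {
  findInterval(at - 1e-12, x) + 1L
}

# Count events of sorted `x` in half-open windows [from, to).
count_in_window <- function(x, from, to) {
  findInterval(to - 1e-12, x) - findInterval(from - 1e-12, x)
}

# Homogeneous Poisson process on [t0, t1) at `rate` Hz.
rpoisson_process <- function(rate, t0, t1) {
  dur <- t1 - t0
  if (dur <= 0 || rate <= 0) return(numeric(0))
  n <- rpois(1L, rate * dur)
  sort(runif(n, t0, t1))
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
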