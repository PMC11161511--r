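# Peri-event time histograms for point processes (spikes, licks) and
# baseline z-scoring.

#' Peri-event time histogram of a point process
#'
#' Bins event-aligned times of a point process (spike or lick times)
#' into a trial-averaged rate in Hz, optionally smoothed with a
#' Gaussian kernel. Windows are half-open `[window[1], window[2])`
#' relative to each alignment event.
#'
#' @param times sorted point-process times, seconds.
#' @param events alignment event times, seconds (non-empty).
#' @param window two-element window relative to the events, seconds.
#' @param binsize bin width, seconds.
#' @param kernel_sd SD of the Gaussian smoothing kernel, seconds;
#'   0 disables smoothing.
#' @param keep_trials keep the per-trial count matrix in the result?
#' @return Object of class `peth`: `bin_centers` (s), `rate` (Hz, or
#'   z-units after [zscore_peth()]), `n_events`, `binsize`, `kernel_sd`,
#'   `zscored`, `degenerate`, and optionally `trials` (event x bin
#'   count matrix).
#' @export
event_peth <- function(times, events, window = c(-2, 2), binsize = 0.01,
                       kernel_sd = 0, keep_trials = TRUE) {
  if (length(events) == 0L) stop_config("events must be non-empty")
  if (window[1] >= window[2]) stop_config("window must satisfy min < max")
  if (binsize <= 0) stop_config("binsize must be > 0")
  times <- sort(times)
  n_bins <- as.integer(round(diff(window) / binsize))
  if (n_bins < 1L) stop_config("window shorter than one bin")
  edges <- window[1] + seq.int(0L, n_bins) * binsize
  centers <- (edges[-1L] + edges[-length(edges)]) / 2

  counts <- matrix(0L, nrow = length(events), ncol = n_bins)
  lo <- findInterval(events + window[1] - 1e-12, times)
  hi <- findInterval(events + window[2] - 1e-12, times)
  for (i in seq_along(events)) {
    if (hi[i] > lo[i]) {
      rel <- times[(lo[i] + 1L):hi[i]] - events[i]
      b <- pmin(pmax(floor((rel - window[1]) / binsize) + 1L, 1L), n_bins)
      tab <- tabulate(b, nbins = n_bins)
      counts[i, ] <- tab
    }
  }
  rate <- colMeans(counts) / binsize
  if (kernel_sd > 0) rate <- gauss_smooth(rate, kernel_sd / binsize)
  structure(list(bin_centers = centers, rate = rate,
                 n_events = length(events), binsize = binsize,
                 kernel_sd = kernel_sd, baseline_window = NULL,
                 zscored = FALSE, degenerate = FALSE,
                 trials = if (keep_trials) counts else NULL),
            class = "peth")
}

#' Z-score a PETH by a baseline window
#'
#' Normalizes the rate by the mean and standard deviation of the bins
#' falling in `baseline_window`, so that baseline bins have mean 0 and
#' SD 1 by construction. A baseline with (numerically) zero variance is
#' flagged `degenerate` and only centred (divided by 1), never silently
#' divided by 0; degenerate PETHs should be excluded from population
#' averages.
#'
#' @param peth a [event_peth()] result (rate in Hz).
#' @param baseline_window two-element window in seconds relative to the
#'   alignment event, default 1 s before it.
#' @return The `peth` with `rate` in z-units, `zscored = TRUE`, and
#'   `baseline_mean` / `baseline_sd` recorded.
#' @export
zscore_peth <- function(peth, baseline_window = c(-1, 0)) {
  stopifnot(inherits(peth, "peth"))
  if (isTRUE(peth$zscored)) stop_config("peth is already z-scored")
  in_base <- peth$bin_centers >= baseline_window[1] &
    peth$bin_centers < baseline_window[2]
  if (!any(in_base)) stop_config("baseline_window contains no bins")
  m <- mean(peth$rate[in_base])
  s <- sd(peth$rate[in_base])
  degenerate <- !is.finite(s) || s < 1e-9
  peth$rate <- (peth$rate - m) / if (degenerate) 1 else s
  peth$baseline_window <- baseline_window
  peth$baseline_mean <- m
  peth$baseline_sd <- if (degenerate) NA_real_ else s
  peth$zscored <- TRUE
  peth$degenerate <- degenerate
  peth
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("PETH: %d bins of %.3g s over [%.2f, %.2f] s, %d events%s%s\n",
              length(x$bin_centers), x$binsize, min(x$bin_centers) - x$binsize / 2,
              max(x$bin_centers) + x$binsize / 2, x$n_events,
              if (x$zscored) ", z-scored" else "",
              if (x$degenerate) " [degenerate baseline]" else ""))
  invisible(x)
}
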