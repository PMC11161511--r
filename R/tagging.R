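# Optogenetic identification of units: first-spike latency
# distributions, Jensen-Shannon divergence, the stimulus-associated
# spike-latency test (SALT), and the tagging decision with a
# spike-shape correlation gate.

#' Jensen-Shannon divergence between two histograms
#'
#' `JSD(P, Q) = H((P+Q)/2) - (H(P) + H(Q))/2` with base-2 entropy
#' (`0 * log 0 = 0`), i.e. the information radius: symmetric,
#' non-negative, and at most 1 bit.
#'
#' @param p,q probability vectors over the same bins (each summing to 1
#'   within 1e-12).
#' @return Divergence in bits.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop_config("histograms must share the same bins")
  if (any(p < 0) || any(q < 0)) stop_config("histogram mass must be non-negative")
  if (abs(sum(p) - 1) > 1e-12 || abs(sum(q) - 1) > 1e-12)
    stop_config("histograms must sum to 1")
  h <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  h((p + q) / 2) - (h(p) + h(q)) / 2
}

#' First-spike latencies in a set of windows
#'
#' For each half-open window `[start, start + window_length)` returns
#' the latency of the first spike inside it, or `NA` when the window
#' contains no spike.
#'
#' @param spikes sorted spike times, seconds.
#' @param window_starts window start times, seconds; must be
#'   non-overlapping.
#' @param window_length window length, seconds.
#' @return Numeric vector of latencies in seconds (`NA` = no spike).
#' @export
first_spike_latencies <- function(spikes, window_starts, window_length) {
  spikes <- spike_times(spikes)
  window_starts <- sort(window_starts)
  if (length(window_starts) > 1L &&
      any(diff(window_starts) < window_length - 1e-12))
    stop_config("windows overlap")
  idx <- first_at_or_after(spikes, window_starts)
  lat <- rep(NA_real_, length(window_starts))
  hit <- idx <= length(spikes)
  lat[hit] <- spikes[idx[hit]] - window_starts[hit]
  lat[!is.na(lat) & lat >= window_length - 1e-12] <- NA_real_
  lat
}

# Latency histogram over `bin` wide bins spanning [0, window) plus a
# terminal "no spike" bin; normalized to probability mass.
latency_histogram <- function(latencies, window, bin) {
  n_bins <- as.integer(round(window / bin))
  # epsilon guards the bin edges against float error in time differences
  b <- pmin(floor(latencies / bin + 1e-6) + 1L, n_bins)
  counts <- tabulate(b[!is.na(latencies)], nbins = n_bins)
  counts <- c(counts, sum(is.na(latencies)))
  counts / length(latencies)
}

#' Stimulus-associated spike-latency test (SALT)
#'
#' Tests whether the distribution of first-spike latencies after light
#' pulses differs from spontaneous activity. One latency histogram is
#' built from equal-length windows starting at each pulse onset, and
#' `n_baseline` histograms from windows tiled over the pulse-free
#' baseline epochs; windows without a spike contribute mass to a
#' dedicated "no spike" bin. Every histogram is built from the same
#' number of windows (pulses or baseline windows are subsampled as
#' needed), making all histograms exchangeable under the null. Each
#' histogram is scored by its median Jensen-Shannon divergence to all
#' others, and the p-value is the rank of the test histogram's score
#' among all histograms, so significance means the post-pulse latency
#' distribution is an outlier relative to spontaneous variability.
#' Units with p < 0.01 are considered light-activated.
#'
#' @param spikes spike train (object or sorted times, seconds).
#' @param pulse_times laser pulse onset times, seconds.
#' @param baseline_epochs two-element vector or matrix of rows
#'   `c(start, end)` delimiting pulse-free epochs, seconds.
#' @param test_window post-pulse window length, seconds (default 10
#'   ms).
#' @param n_baseline number of baseline histograms (default 100; the
#'   smallest attainable p is `1 / (n_baseline + 1)`).
#' @param bin latency bin width, seconds (default 1 ms).
#' @param seed seed for the window subsampling.
#' @return Object of class `tagging_result`: `p_salt`, `divergence`
#'   (median test-versus-baseline JSD, bits), `median_latency_ms`,
#'   `jitter_ms` (median absolute deviation), `tagged`
#'   (`p_salt < 0.01`), `n_windows` per histogram.
#' @export
salt <- function(spikes, pulse_times, baseline_epochs,
                 test_window = 0.010, n_baseline = 100L, bin = 0.001,
                 seed = 1L) {
  times <- spike_times(spikes)
  if (length(pulse_times) < 2L) stop_config("need at least 2 pulses")
  ep <- if (is.matrix(baseline_epochs)) baseline_epochs
        else matrix(as.numeric(baseline_epochs), ncol = 2L, byrow = TRUE)
  base_starts <- unlist(lapply(seq_len(nrow(ep)), function(r) {
    if (ep[r, 2] - ep[r, 1] < test_window) return(numeric(0))
    seq(ep[r, 1], ep[r, 2] - test_window, by = test_window)
  }))
  m_base <- floor(length(base_starts) / n_baseline)
  if (m_base < 1L)
    stop_config("baseline epochs too short to tile %d windows of %g s",
                n_baseline, test_window)
  n_win <- min(length(pulse_times), m_base)

  with_seed(seed, {
    test_starts <- if (length(pulse_times) > n_win)
      sort(sample(pulse_times, n_win)) else sort(pulse_times)
    base_starts <- sample(base_starts)  # spread histograms over the epoch
    hist_set <- matrix(0, nrow = as.integer(round(test_window / bin)) + 1L,
                       ncol = n_baseline + 1L)
    lat_test <- first_spike_latencies(times, test_starts, test_window)
    hist_set[, 1L] <- latency_histogram(lat_test, test_window, bin)
    for (g in seq_len(n_baseline)) {
      st <- sort(base_starts[((g - 1L) * n_win + 1L):(g * n_win)])
      hist_set[, g + 1L] <- latency_histogram(
        first_spike_latencies(times, st, test_window), test_window, bin)
    }

    nh <- ncol(hist_set)
    D <- matrix(0, nh, nh)
    for (i in seq_len(nh - 1L)) for (j in (i + 1L):nh) {
      D[i, j] <- D[j, i] <- js_divergence(hist_set[, i], hist_set[, j])
    }
    score <- vapply(seq_len(nh), function(h) median(D[h, -h]), 0)
    p <- (1 + sum(score[-1L] >= score[1L])) / nh

    lat_all <- first_spike_latencies(times, sort(pulse_times), test_window)
    lat_obs <- lat_all[!is.na(lat_all)] * 1000
    structure(list(p_salt = p,
                   divergence = median(D[1L, -1L]),
                   median_latency_ms = if (length(lat_obs)) median(lat_obs) else NA_real_,
                   jitter_ms = if (length(lat_obs) > 1L) mad(lat_obs) else NA_real_,
                   tagged = p < 0.01,
                   n_windows = n_win, n_baseline = n_baseline,
                   test_window_ms = test_window * 1000),
              class = "tagging_result")
  })
}

#' Final tagging decision with waveform gate
#'
#' A unit is accepted as optogenetically identified when the SALT
#' p-value is below `alpha` (default 0.01) and the Pearson correlation
#' between its light-evoked and spontaneous mean waveforms is at least
#' `min_waveform_r` (default 0.84, the empirical floor of accepted
#' units). With no waveform correlation available the decision is made
#' on the p-value alone and flagged.
#'
#' @param result a [salt()] result.
#' @param waveform_correlation Pearson r between light-evoked and
#'   spontaneous mean waveforms, or `NULL` if unavailable.
#' @param alpha SALT significance threshold.
#' @param min_waveform_r waveform-correlation threshold.
#' @return The `tagging_result` updated with `tagged`,
#'   `waveform_correlation`, `waveform_gated` and `qc` (named summary
#'   vector).
#' @export
tag_decision <- function(result, waveform_correlation = NULL,
                         alpha = 0.01, min_waveform_r = 0.84) {
  stopifnot(inherits(result, "tagging_result"))
  p_ok <- result$p_salt < alpha
  if (is.null(waveform_correlation)) {
    result$tagged <- p_ok
    result$waveform_correlation <- NA_real_
    result$waveform_gated <- FALSE
    warning("no waveform correlation supplied; tagging decided on p alone")
  } else {
    result$waveform_correlation <- waveform_correlation
    result$waveform_gated <- TRUE
    result$tagged <- p_ok && waveform_correlation >= min_waveform_r
  }
  result$qc <- c(p_salt = result$p_salt,
                 divergence_bits = result$divergence,
                 median_latency_ms = result$median_latency_ms,
                 jitter_ms = result$jitter_ms,
                 waveform_r = result$waveform_correlation)
  result
}

#' Waveform correlation between light-evoked and spontaneous spikes
#'
#' @param light,spontaneous mean waveforms (numeric vectors or matrices
#'   flattened channel-wise).
#' @return Pearson correlation coefficient.
#' @export
waveform_correlation <- function(light, spontaneous) {
  cor(as.numeric(light), as.numeric(spontaneous))
}

#' @export
print.tagging_result <- function(x, ...) {
  cat(sprintf(
    "SALT: p = %.4g, divergence = %.3f bits, latency %.2f ms (MAD %.2f), %s\n",
    x$p_salt, x$divergence, x$median_latency_ms, x$jitter_ms,
    if (isTRUE(x$tagged)) "TAGGED" else "not tagged"))
  invisible(x)
}
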