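# Fiber-photometry processing chain: zero-phase Butterworth filtering,
# isosbestic least-squares fit, dF/F, detrending, and event-aligned
# z-scored averaging.

#' Construct a two-channel photometry recording
#'
#' @param f465 calcium-dependent channel, fluorescence units.
#' @param f405 isosbestic channel, same length.
#' @param fs sampling rate, Hz (> 40 so a 20 Hz low-pass is supported).
#' @param t0 time of the first sample, seconds.
#' @return Object of class `photometry_recording` with `t`, `f465`,
#'   `f405`, `fs`.
#' @export
photometry_recording <- function(f465, f405, fs, t0 = 0) {
  if (length(f465) != length(f405)) stop_config("channels must have equal length")
  if (fs <= 40) stop_config("fs must exceed 40 Hz")
  if (anyNA(f465) || anyNA(f405)) stop_config("channels must have no missing samples")
  structure(list(t = t0 + (seq_along(f465) - 1L) / fs,
                 f465 = as.numeric(f465), f405 = as.numeric(f405), fs = fs),
            class = "photometry_recording")
}

# Zero-phase Butterworth filter (forward-backward). The mean is removed
# and the series odd-reflection padded before filtering so that startup
# transients of the recursion do not leak into the output; a constant
# input passes a low-pass unchanged and maps to zero under a high-pass.
butter_filtfilt <- function(x, fs, cutoff, type, order = 4L) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop_config("cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoff / (fs / 2), type = type)
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  pad <- min(n - 1L, max(as.integer(ceiling(3 * fs / cutoff)), 3L * (order + 1L)))
  pre <- 2 * xc[1] - xc[(pad + 1L):2L]
  post <- 2 * xc[n] - xc[(n - 1L):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, xc, post)))
  y <- y[(pad + 1L):(pad + n)]
  if (type == "low") y + mu else y
}

#' Low-pass filter a photometry recording
#'
#' Zero-phase Butterworth low-pass (default 20 Hz, order 4) applied to
#' both channels to remove high-frequency noise; DC gain is 1.
#'
#' @param recording a [photometry_recording()].
#' @param cutoff cutoff frequency, Hz.
#' @param order filter order.
#' @return The recording with both channels filtered.
#' @export
lowpass <- function(recording, cutoff = 20, order = 4L) {
  stopifnot(inherits(recording, "photometry_recording"))
  recording$f465 <- butter_filtfilt(recording$f465, recording$fs, cutoff, "low", order)
  recording$f405 <- butter_filtfilt(recording$f405, recording$fs, cutoff, "low", order)
  recording$lowpass_hz <- cutoff
  recording
}

#' Least-squares fit of the isosbestic channel
#'
#' Ordinary least squares of `f465` on `f405`, aligning the isosbestic
#' baseline intensity to the calcium-dependent channel; the fitted
#' trace `slope * f405 + intercept` is the motion/autofluorescence
#' reference for dF/F.
#'
#' @param f465,f405 numeric channel vectors.
#' @param allow_intercept_only with a constant `f405`, fall back to an
#'   intercept-only fit instead of failing.
#' @return List with `slope`, `intercept`, `f405_fitted`.
#' @export
fit_isosbestic <- function(f465, f405, allow_intercept_only = FALSE) {
  v <- var(f405)
  if (!is.finite(v) || v < 1e-24) {
    if (!allow_intercept_only)
      stop_config("f405 has (numerically) zero variance; isosbestic fit is degenerate")
    return(list(slope = 0, intercept = mean(f465),
                f405_fitted = rep(mean(f465), length(f465))))
  }
  slope <- cov(f465, f405) / v
  intercept <- mean(f465) - slope * mean(f405)
  list(slope = slope, intercept = intercept,
       f405_fitted = slope * f405 + intercept)
}

#' Fractional fluorescence change (dF/F)
#'
#' `dff = (f465 - f405_fitted) / f405_fitted * 100`, in percent,
#' removing shared motion and autofluorescence.
#'
#' @param f465 calcium-dependent channel.
#' @param f405_fitted fitted isosbestic reference (> 0 everywhere).
#' @return Numeric dF/F trace in percent.
#' @export
compute_dff <- function(f465, f405_fitted) {
  if (any(f405_fitted <= 0))
    stop_config("fitted isosbestic trace must be positive everywhere (failed fit or bleach-through)")
  (f465 - f405_fitted) / f405_fitted * 100
}

#' High-pass filter a dF/F trace
#'
#' Zero-phase Butterworth high-pass (default 0.2 Hz) removing the slow
#' baseline decrease (bleaching residual). Recordings shorter than
#' `3 / cutoff` seconds are returned unfiltered with a warning.
#'
#' @param dff numeric dF/F trace.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz.
#' @param order filter order.
#' @return Filtered trace.
#' @export
highpass <- function(dff, fs, cutoff = 0.2, order = 4L) {
  if (length(dff) / fs < 3 / cutoff) {
    warning("recording shorter than 3/cutoff; high-pass skipped")
    return(dff)
  }
  butter_filtfilt(dff, fs, cutoff, "high", order)
}

#' Full photometry preprocessing chain
#'
#' Low-pass both raw channels, fit the isosbestic channel, compute
#' dF/F, then high-pass the dF/F to remove the bleaching trend.
#'
#' @param recording a [photometry_recording()].
#' @param lowpass_hz,highpass_hz filter cutoffs (Hz); `NA` skips a
#'   stage.
#' @param order Butterworth order for both filters.
#' @return Object of class `dff_trace`: `t`, `dff` (percent), `fs`,
#'   `fit` (slope/intercept), `filters`.
#' @export
process_photometry <- function(recording, lowpass_hz = 20, highpass_hz = 0.2,
                               order = 4L) {
  stopifnot(inherits(recording, "photometry_recording"))
  rec <- if (is.finite(lowpass_hz)) lowpass(recording, lowpass_hz, order) else recording
  fit <- fit_isosbestic(rec$f465, rec$f405)
  dff <- compute_dff(rec$f465, fit$f405_fitted)
  if (is.finite(highpass_hz)) dff <- highpass(dff, rec$fs, highpass_hz, order)
  structure(list(t = rec$t, dff = dff, fs = rec$fs,
                 fit = fit[c("slope", "intercept")],
                 filters = list(lowpass_hz = lowpass_hz,
                                highpass_hz = highpass_hz, order = order)),
            class = "dff_trace")
}

#' Event-aligned, z-scored dF/F average
#'
#' Extracts per-event dF/F snippets, smooths each with a Gaussian
#' kernel (default 100 ms SD), averages across events, and z-scores the
#' average by the mean and SD of the baseline portion (1 s before the
#' baseline-anchoring events, which default to the alignment events but
#' should be the cue onsets when aligning to reinforcement). Events too
#' close to the recording edges are dropped and counted.
#'
#' @param x a `dff_trace` (or list with `t`, `dff`, `fs`).
#' @param events alignment event times, seconds.
#' @param window two-element window relative to the events, seconds.
#' @param kernel_sd Gaussian smoothing SD, seconds.
#' @param baseline_events events anchoring the baseline window
#'   (default: `events`).
#' @param baseline_window baseline window, seconds, relative to
#'   `baseline_events`.
#' @return Object of class `peth` (z-units) with additional fields
#'   `trials` (event x sample matrix of smoothed dF/F snippets),
#'   `n_dropped`.
#' @export
align_average <- function(x, events, window = c(-1, 2), kernel_sd = 0.1,
                          baseline_events = events,
                          baseline_window = c(-1, 0)) {
  fs <- x$fs
  snip <- function(ev, win) {
    offs <- seq.int(round(win[1] * fs), round(win[2] * fs) - 1L)
    idx0 <- round((ev - x$t[1]) * fs) + 1L
    ok <- idx0 + offs[1] >= 1L & idx0 + offs[length(offs)] <= length(x$dff)
    m <- t(vapply(idx0[ok], function(i0) x$dff[i0 + offs], numeric(length(offs))))
    if (kernel_sd > 0) m <- t(apply(m, 1L, gauss_smooth, sd_bins = kernel_sd * fs))
    list(m = m, dropped = sum(!ok), centers = (offs + 0.5) / fs)
  }
  events <- events[!is.na(events)]
  baseline_events <- baseline_events[!is.na(baseline_events)]
  if (length(events) == 0L) stop_config("events must be non-empty")
  s_test <- snip(events, window)
  s_base <- snip(baseline_events, baseline_window)
  if (nrow(s_test$m) == 0L) stop_config("all events fall outside the recording")
  mean_trace <- colMeans(s_test$m)
  base_trace <- colMeans(s_base$m)
  m <- mean(base_trace)
  s <- sd(base_trace)
  degenerate <- !is.finite(s) || s < 1e-9
  z <- (mean_trace - m) / if (degenerate) 1 else s
  structure(list(bin_centers = s_test$centers, rate = z,
                 n_events = nrow(s_test$m), binsize = 1 / fs,
                 kernel_sd = kernel_sd, baseline_window = baseline_window,
                 baseline_mean = m,
                 baseline_sd = if (degenerate) NA_real_ else s,
                 zscored = TRUE, degenerate = degenerate,
                 trials = s_test$m,
                 n_dropped = s_test$dropped + s_base$dropped),
            class = "peth")
}
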