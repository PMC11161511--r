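# Synthetic two-channel photometry: event kernels on an exponentially
# bleaching baseline, with motion artifact shared between the
# calcium-dependent and isosbestic channels.

#' Photometry simulation configuration
#'
#' @param fs sampling rate of the demodulated traces, Hz (> 40 so the
#'   20 Hz low-pass is supported).
#' @param bleach_tau exponential bleaching time constant, seconds.
#' @param kernel_rise,kernel_decay rise and decay time constants of the
#'   calcium event kernel (difference of exponentials), seconds;
#'   `kernel_rise < kernel_decay`.
#' @param motion_amp SD of the band-limited motion artifact,
#'   fluorescence units.
#' @param motion_share_405 coupling of the motion artifact into the
#'   isosbestic channel (1 = perfectly shared).
#' @param noise_sd SD of per-channel white measurement noise,
#'   fluorescence units.
#' @param gain coupling of the latent neural activity into the
#'   calcium-dependent channel (fractional modulation per unit
#'   activity).
#' @param f0 initial baseline fluorescence of the 465 channel.
#' @param iso_scale baseline scale of the isosbestic channel relative
#'   to the 465 channel.
#' @param motion_bandwidth_hz low-pass corner of the motion artifact,
#'   Hz.
#' @param seed integer random seed.
#' @return Object of class `photometry_config`.
#' @export
photometry_config <- function(fs = 1000, bleach_tau = 600,
                              kernel_rise = 0.1, kernel_decay = 1.0,
                              motion_amp = 0.5, motion_share_405 = 1,
                              noise_sd = 0.02, gain = 0.1,
                              f0 = 100, iso_scale = 0.8,
                              motion_bandwidth_hz = 2, seed = 1L) {
  if (fs <= 40) stop_config("fs must exceed 40 Hz to support the 20 Hz low-pass")
  if (kernel_rise >= kernel_decay) stop_config("kernel_rise must be < kernel_decay")
  if (motion_amp < 0 || noise_sd < 0 || gain < 0 || f0 <= 0)
    stop_config("amplitudes must be >= 0 and f0 > 0")
  structure(list(fs = fs, bleach_tau = bleach_tau,
                 kernel_rise = kernel_rise, kernel_decay = kernel_decay,
                 motion_amp = motion_amp, motion_share_405 = motion_share_405,
                 noise_sd = noise_sd, gain = gain, f0 = f0,
                 iso_scale = iso_scale,
                 motion_bandwidth_hz = motion_bandwidth_hz,
                 seed = as.integer(seed)),
            class = "photometry_config")
}

# Difference-of-exponentials kernel normalized to unit peak.
calcium_kernel <- function(fs, rise, decay) {
  tt <- seq(0, decay * 6, by = 1 / fs)
  k <- exp(-tt / decay) - exp(-tt / rise)
  k / max(k)
}

#' Simulate a two-channel photometry recording
#'
#' The latent activity is a sum of calcium event kernels at the
#' session's cue, reward and punishment times, scaled by the event
#' amplitudes in `profile$gains - 1` (so gain 1 = no response, gain 3 =
#' amplitude 2). The calcium-dependent channel is
#' `B(t) * (1 + gain * a(t)) + motion(t) + noise`, the isosbestic
#' channel `iso_scale * B(t) + motion_share_405 * motion(t) + noise`,
#' with `B(t)` an exponentially bleaching baseline and `motion(t)`
#' band-limited noise shared between the channels.
#'
#' @param trials trial table from [generate_session()].
#' @param profile a [response_profile()] providing per-event amplitudes.
#' @param pconfig a [photometry_config()].
#' @param duration recording length, seconds; defaults to the last
#'   event + 10 s.
#' @return A [photometry_recording()] with the ground-truth latent
#'   activity attached as attribute `activity`.
#' @export
generate_photometry <- function(trials, profile, pconfig, duration = NULL) {
  stopifnot(inherits(pconfig, "photometry_config"),
            inherits(profile, "response_profile"))
  ev <- session_event_times(trials)
  if (is.null(duration)) {
    last <- suppressWarnings(max(0, unlist(ev), na.rm = TRUE))
    duration <- last + 10
  }
  fs <- pconfig$fs
  n <- as.integer(round(duration * fs))
  tt <- (seq_len(n) - 1L) / fs

  kern <- calcium_kernel(fs, pconfig$kernel_rise, pconfig$kernel_decay)
  activity <- numeric(n)
  for (type in names(profile$gains)) {
    amp <- unname(profile$gains[[type]]) - 1
    if (amp == 0) next
    times <- ev[[type]]
    times <- times[!is.na(times)]
    for (e in times) {
      i0 <- as.integer(round(e * fs)) + 1L
      if (i0 > n) next
      idx <- i0:min(n, i0 + length(kern) - 1L)
      activity[idx] <- activity[idx] + amp * kern[seq_along(idx)]
    }
  }

  with_seed(pconfig$seed, {
    bleach <- pconfig$f0 * exp(-tt / pconfig$bleach_tau)
    motion <- if (pconfig$motion_amp > 0) {
      raw <- butter_filtfilt(rnorm(n), fs, pconfig$motion_bandwidth_hz, "low", 2L)
      raw / max(sd(raw), 1e-12) * pconfig$motion_amp
    } else numeric(n)
    noise465 <- if (pconfig$noise_sd > 0) rnorm(n, 0, pconfig$noise_sd) else numeric(n)
    noise405 <- if (pconfig$noise_sd > 0) rnorm(n, 0, pconfig$noise_sd) else numeric(n)
    f465 <- bleach * (1 + pconfig$gain * activity) + motion + noise465
    f405 <- pconfig$iso_scale * bleach + pconfig$motion_share_405 * motion + noise405
    rec <- photometry_recording(f465, f405, fs)
    attr(rec, "activity") <- activity
    rec
  })
}
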