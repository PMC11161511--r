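# Synthetic spike trains: event-locked inhomogeneous Poisson units with
# controllable latency, jitter, gain, adaptation and bursting, plus
# photostimulation (tagging) epochs.

#' Response profile of a simulated unit
#'
#' Parameterizes how a unit responds to task events. Within
#' `[latency, latency + response_duration]` after the k-th presentation
#' of event type `e`, the firing rate is
#' `baseline_rate * gains[e] * adaptation^(k-1)`; elsewhere it is
#' `baseline_rate`. A `burstiness` fraction of spikes is emitted as
#' short bursts (2-4 spikes, intra-burst intervals 3-8 ms).
#'
#' @param baseline_rate tonic rate, Hz (> 0).
#' @param gains named multiplicative rate factors per event type
#'   (`cue`, `reward`, `punishment`); 1 means no response, < 1 inhibition.
#' @param latency mean response onset after the event, seconds.
#' @param jitter SD of the response onset, seconds.
#' @param response_duration response window length, seconds.
#' @param burstiness fraction of spikes emitted in bursts, in [0, 1].
#' @param adaptation per-presentation multiplicative decay of the event
#'   gain's excess over baseline, in (0, 1]. 1 disables adaptation.
#' @return Object of class `response_profile`.
#' @export
response_profile <- function(baseline_rate = 5,
                             gains = c(cue = 1, reward = 1, punishment = 1),
                             latency = 0.02, jitter = 0.005,
                             response_duration = 0.2,
                             burstiness = 0, adaptation = 1) {
  if (baseline_rate <= 0) stop_config("baseline_rate must be > 0")
  if (any(gains < 0)) stop_config("gains must be >= 0")
  if (burstiness < 0 || burstiness > 1) stop_config("burstiness must be in [0, 1]")
  if (adaptation <= 0 || adaptation > 1) stop_config("adaptation must be in (0, 1]")
  if (latency < 0 || jitter < 0 || response_duration <= 0)
    stop_config("latency/jitter must be >= 0 and response_duration > 0")
  structure(list(baseline_rate = baseline_rate, gains = gains,
                 latency = latency, jitter = jitter,
                 response_duration = response_duration,
                 burstiness = burstiness, adaptation = adaptation),
            class = "response_profile")
}

# Event times per type from a trial table: cue onsets plus reward /
# punishment outcome times.
session_event_times <- function(trials) {
  list(cue = trials$cue_onset,
       reward = trials$outcome_time[trials$outcome == "reward"],
       punishment = trials$outcome_time[trials$outcome == "punishment"])
}

#' Simulate an event-locked spike train
#'
#' Inhomogeneous Poisson spiking generated by thinning: the rate is
#' `baseline_rate` except inside response windows after events whose
#' gain differs from 1 (see [response_profile()]). Overlapping windows
#' take the strongest modulation. Spike times are sorted and unique at
#' 0.1 ms resolution.
#'
#' @param trials trial table as produced by [generate_session()] (the
#'   `trials` element), or `NULL` to simulate a stationary unit.
#' @param profile a [response_profile()].
#' @param duration recording length in seconds; defaults to the last
#'   trial event + 5 s.
#' @param seed integer random seed.
#' @return Object of class `spike_train`: list with `times` (sorted
#'   seconds), `duration`, and the `profile` used.
#' @export
generate_spike_train <- function(trials, profile, duration = NULL, seed = 1L) {
  stopifnot(inherits(profile, "response_profile"))
  ev <- if (is.null(trials) || nrow(trials) == 0L) {
    list(cue = numeric(0), reward = numeric(0), punishment = numeric(0))
  } else session_event_times(trials)
  if (is.null(duration)) {
    last <- suppressWarnings(max(0, unlist(ev), na.rm = TRUE))
    duration <- last + 5
  }
  if (duration <= 0) stop_config("duration must be > 0")

  with_seed(seed, {
    # response windows, one row per (event type, presentation)
    win <- list()
    for (type in names(profile$gains)) {
      g <- unname(profile$gains[[type]])
      times <- ev[[type]]
      times <- times[!is.na(times)]
      if (g == 1 || length(times) == 0L) next
      onset <- times + profile$latency +
        pmax(rnorm(length(times), 0, profile$jitter), -profile$latency)
      mult <- g * profile$adaptation^(seq_along(times) - 1)
      win[[type]] <- cbind(onset, onset + profile$response_duration, mult)
    }
    win <- do.call(rbind, win)

    rmax <- profile$baseline_rate * max(1, if (is.null(win)) 1 else max(win[, 3]))
    cand <- rpoisson_process(rmax, 0, duration)
    if (length(cand) && !is.null(win)) {
      mult <- rep(1, length(cand))
      for (r in seq_len(nrow(win))) {
        inside <- cand >= win[r, 1] & cand < win[r, 2]
        # strongest modulation wins where windows overlap
        mult[inside] <- pmax(mult[inside], win[r, 3], na.rm = TRUE)
        low <- inside & win[r, 3] < 1
        mult[low] <- pmin(mult[low], win[r, 3])
      }
      keep <- runif(length(cand)) < profile$baseline_rate * mult / rmax
      spikes <- cand[keep]
    } else {
      spikes <- cand[runif(length(cand)) < profile$baseline_rate / rmax]
    }

    if (profile$burstiness > 0 && length(spikes)) {
      burst_parent <- runif(length(spikes)) < profile$burstiness
      extra <- lapply(spikes[burst_parent], function(t0) {
        n_extra <- sample(1:3, 1L)
        t0 + cumsum(runif(n_extra, 0.003, 0.008))
      })
      spikes <- c(spikes, unlist(extra))
    }
    spikes <- canonical_times(spikes)
    spikes <- spikes[spikes >= 0 & spikes < duration]

    structure(list(times = spikes, duration = duration, profile = profile),
              class = "spike_train")
  })
}

#' Simulate an optogenetic tagging epoch
#'
#' Emulates the tagging protocol: trains of 1 ms laser pulses at
#' `pulse_hz` for `block_duration` seconds, separated by `pause`
#' seconds, repeated `n_blocks` times, preceded by a pulse-free baseline
#' epoch. A tagged unit fires one light-evoked spike per pulse with
#' probability `reliability` at `latency` +/- `jitter` on top of its
#' baseline Poisson spiking; an untagged unit spikes independently of
#' the pulses.
#'
#' @param tagged logical: does the unit respond to light?
#' @param latency light-evoked spike latency, seconds (default 3 ms).
#' @param jitter SD of the evoked latency, seconds (default 0.5 ms).
#' @param reliability per-pulse spiking probability in [0, 1].
#' @param baseline_rate tonic Poisson rate, Hz.
#' @param n_blocks number of pulse blocks (protocol uses 20-30).
#' @param pulse_hz pulse rate within a block, Hz.
#' @param block_duration,pause block length and inter-block pause, s.
#' @param baseline_duration pulse-free epoch preceding stimulation, s.
#' @param seed integer random seed.
#' @return List of class `tagging_epoch` with `pulses` (pulse onset
#'   times), `spikes` (a `spike_train`), and `baseline_epoch`
#'   (start/end of the pulse-free epoch).
#' @export
generate_tagging_epoch <- function(tagged, latency = 0.003, jitter = 5e-4,
                                   reliability = 0.9, baseline_rate = 10,
                                   n_blocks = 25L, pulse_hz = 20,
                                   block_duration = 2, pause = 3,
                                   baseline_duration = 120, seed = 1L) {
  if (reliability < 0 || reliability > 1) stop_config("reliability must be in [0, 1]")
  if (baseline_rate <= 0) stop_config("baseline_rate must be > 0")
  if (n_blocks < 1) stop_config("n_blocks must be >= 1")
  per_block <- as.integer(round(block_duration * pulse_hz))
  starts <- baseline_duration + (seq_len(n_blocks) - 1L) * (block_duration + pause)
  pulses <- as.vector(vapply(starts, function(s) s + (seq_len(per_block) - 1L) / pulse_hz,
                             numeric(per_block)))
  t_end <- max(pulses) + pause

  with_seed(seed, {
    spikes <- rpoisson_process(baseline_rate, 0, t_end)
    if (isTRUE(tagged) && reliability > 0) {
      fires <- runif(length(pulses)) < reliability
      evoked <- pulses[fires] + pmax(rnorm(sum(fires), latency, jitter), 1e-4)
      spikes <- c(spikes, evoked)
    }
    spikes <- canonical_times(spikes)
    structure(list(
      pulses = pulses,
      spikes = structure(list(times = spikes, duration = t_end, profile = NULL),
                         class = "spike_train"),
      baseline_epoch = c(0, baseline_duration),
      tagged = isTRUE(tagged) && reliability > 0,
      params = list(latency = latency, jitter = jitter,
                    reliability = reliability, baseline_rate = baseline_rate,
                    n_blocks = n_blocks, pulse_hz = pulse_hz)),
      class = "tagging_epoch")
  })
}

#' Simulate a population of archetypal z-scored response profiles
#'
#' Builds a unit-by-bin matrix of z-scored cue-aligned PETHs drawn from
#' five canonical response archetypes (phasic activation, ramping
#' activation, delayed activation, suppression, non-responsive) plus
#' i.i.d. Gaussian noise. Used to benchmark response clustering: the
#' archetype labels are the clustering ground truth, and tagged flags
#' are concentrated in the first (phasic) archetype.
#'
#' @param n_per units per archetype.
#' @param n_bins bins per PETH (the matrix concatenates the two
#'   cue-aligned PETHs, so it has `2 * n_bins` columns).
#' @param noise_sd SD of the additive noise in z-units.
#' @param p_tagged_first fraction of first-archetype units flagged as
#'   tagged.
#' @param seed integer random seed.
#' @return List with `zpeths` (matrix), `labels` (true archetype per
#'   unit) and `tagged` (logical per unit).
#' @export
simulate_response_archetypes <- function(n_per = 20L, n_bins = 40L,
                                         noise_sd = 0.1,
                                         p_tagged_first = 0.8, seed = 1L) {
  tt <- seq(0, 1, length.out = n_bins)
  bump <- function(mu, sdv, amp) amp * exp(-(tt - mu)^2 / (2 * sdv^2))
  arch <- list(
    phasic    = c(bump(0.15, 0.05, 4), bump(0.15, 0.05, 4)),
    ramp      = c(2 * tt, 2 * tt),
    delayed   = c(bump(0.7, 0.12, 3), bump(0.7, 0.12, 1)),
    suppress  = c(-bump(0.3, 0.15, 2), -bump(0.3, 0.15, 2)),
    flat      = rep(0, 2L * n_bins))
  with_seed(seed, {
    labels <- rep(seq_along(arch), each = n_per)
    z <- do.call(rbind, lapply(labels, function(a) arch[[a]]))
    z <- z + matrix(rnorm(length(z), 0, noise_sd), nrow = nrow(z))
    tagged <- logical(length(labels))
    first <- which(labels == 1L)
    tagged[first] <- runif(length(first)) < p_tagged_first
    list(zpeths = z, labels = labels, tagged = tagged)
  })
}
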