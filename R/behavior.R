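# Lick-based behavioral readouts: lick PETHs, anticipatory lick rates,
# reaction times and the auROC time-course with bootstrap permutation
# significance.

#' Lick PETH
#'
#' [event_peth()] for lick times, with a 100 ms default smoothing
#' kernel.
#'
#' @param licks sorted lick times, seconds.
#' @inheritParams event_peth
#' @return A `peth` object (lick rate in Hz).
#' @export
lick_peth <- function(licks, events, window = c(-2, 3), binsize = 0.01,
                      kernel_sd = 0.1, keep_trials = TRUE) {
  event_peth(licks, events, window, binsize, kernel_sd, keep_trials)
}

#' Anticipatory lick rate
#'
#' Lick count in a window after cue onset divided by the window length.
#' The default 0.6-1.1 s window covers the half second before the
#' earliest possible reinforcement.
#'
#' @param licks sorted lick times, seconds.
#' @param cue_onsets cue onset times, seconds (one value per trial).
#' @param window two-element window in seconds from cue onset.
#' @return Numeric vector of rates in Hz, one per trial.
#' @export
anticipatory_rate <- function(licks, cue_onsets, window = c(0.6, 1.1)) {
  if (window[1] >= window[2]) stop_config("window must satisfy min < max")
  count_in_window(sort(licks), cue_onsets + window[1], cue_onsets + window[2]) /
    diff(window)
}

#' Reaction time of the first lick after cue onset
#'
#' @param licks sorted lick times, seconds.
#' @param cue_onsets cue onset times, seconds.
#' @param max_wait censoring horizon, seconds (> 0); trials with no
#'   lick within it return `NA` and should be excluded from averages.
#' @return Numeric vector of latencies in seconds (`NA` = censored).
#' @export
reaction_time <- function(licks, cue_onsets, max_wait = 2) {
  if (max_wait <= 0) stop_config("max_wait must be > 0")
  licks <- sort(licks)
  idx <- first_at_or_after(licks, cue_onsets)
  rt <- rep(NA_real_, length(cue_onsets))
  hit <- idx <= length(licks)
  rt[hit] <- licks[idx[hit]] - cue_onsets[hit]
  rt[!is.na(rt) & rt >= max_wait] <- NA_real_
  rt
}

#' Area under the ROC curve between two samples
#'
#' Probability that a random draw from `a` exceeds a random draw from
#' `b`, ties counted with half weight (the Mann-Whitney U statistic
#' divided by `n_a * n_b`).
#'
#' @param a,b numeric samples.
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop_config("both samples must be non-empty")
  r <- rank(c(a, b))
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
}

#' auROC time-course with bootstrap permutation test
#'
#' At every time bin, computes the auROC between the per-session values
#' of two groups (by default each session's Cue 1 minus Cue 2 smoothed
#' lick-rate difference) and a permutation p-value obtained by
#' resampling the group labels `n_resamples` times and comparing
#' `|auROC - 0.5|`. With 200 resamplings the smallest attainable p is
#' 1/201; p-values are floored there and the floor is reported. No
#' correction is applied across time bins; contiguous significant spans
#' are flagged instead.
#'
#' @param group_a,group_b numeric matrices, sessions in rows, time bins
#'   in columns (>= 2 sessions each, equal bin count).
#' @param bin_centers optional bin centers in seconds (defaults to
#'   10 ms spacing from 0).
#' @param n_resamples number of label permutations (default 200).
#' @param alpha significance level for the contiguous-span flags.
#' @param seed integer random seed for the permutations.
#' @return Object of class `auroc_timecourse`: data.frame `timecourse`
#'   with `bin_center`, `auroc`, `p`, `significant`; `p_floor`;
#'   `n_resamples`; `spans` (data.frame of contiguous significant
#'   runs).
#' @export
auroc_timecourse <- function(group_a, group_b, bin_centers = NULL,
                             n_resamples = 200L, alpha = 0.05, seed = 1L) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  if (nrow(group_a) < 2L || nrow(group_b) < 2L)
    stop_config("each group needs >= 2 sessions")
  if (ncol(group_a) != ncol(group_b)) stop_config("groups must share time bins")
  n_bins <- ncol(group_a)
  if (is.null(bin_centers)) bin_centers <- (seq_len(n_bins) - 0.5) * 0.01
  na <- nrow(group_a); nb <- nrow(group_b)
  pooled <- rbind(group_a, group_b)

  obs <- vapply(seq_len(n_bins), function(j) auroc(group_a[, j], group_b[, j]), 0)
  with_seed(seed, {
    exceed <- integer(n_bins)
    for (r in seq_len(n_resamples)) {
      idx <- sample.int(na + nb)
      pa <- pooled[idx[seq_len(na)], , drop = FALSE]
      pb <- pooled[idx[(na + 1L):(na + nb)], , drop = FALSE]
      perm <- vapply(seq_len(n_bins), function(j) auroc(pa[, j], pb[, j]), 0)
      exceed <- exceed + (abs(perm - 0.5) >= abs(obs - 0.5) - 1e-12)
    }
    p <- (1 + exceed) / (n_resamples + 1)
  })
  sig <- p < alpha
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  spans <- data.frame(start_s = bin_centers[starts[runs$values]],
                      end_s = bin_centers[ends[runs$values]],
                      n_bins = runs$lengths[runs$values])
  structure(list(timecourse = data.frame(bin_center = bin_centers,
                                         auroc = obs, p = p,
                                         significant = sig),
                 p_floor = 1 / (n_resamples + 1),
                 n_resamples = n_resamples, alpha = alpha,
                 spans = spans),
            class = "auroc_timecourse")
}

#' Per-session cue-difference lick-rate series
#'
#' Builds the per-session quantity entering the ROC comparison: the
#' smoothed Cue 1 minus Cue 2 lick-rate difference over a window from
#' cue onset, sampled at `step` (default 10 ms) resolution. Set
#' `difference = FALSE` to obtain the raw Cue 1 lick-rate series
#' instead.
#'
#' @param session a [generate_session()] result (or a list with
#'   `licks` and `trials`).
#' @param t_max window length from cue onset, seconds (default 1.1 s,
#'   cue to earliest reinforcement).
#' @param step bin width, seconds.
#' @param kernel_sd Gaussian smoothing SD, seconds.
#' @param difference return Cue 1 - Cue 2 difference (default) or the
#'   Cue 1 series alone.
#' @return Numeric vector of length `t_max / step` (one value per time
#'   bin).
#' @export
session_lick_series <- function(session, t_max = 1.1, step = 0.01,
                                kernel_sd = 0.1, difference = TRUE) {
  trials <- session$trials
  rate_for <- function(cue) {
    ev <- trials$cue_onset[trials$cue_id == cue]
    if (length(ev) == 0L) return(rep(0, round(t_max / step)))
    lick_peth(session$licks, ev, window = c(0, t_max), binsize = step,
              kernel_sd = kernel_sd, keep_trials = FALSE)$rate
  }
  if (difference) rate_for(1L) - rate_for(2L) else rate_for(1L)
}
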