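# Synthetic probabilistic Pavlovian conditioning sessions.
#
# Emulates the head-fixed task structure: on each trial a variable
# lick-free foreperiod (truncated exponential, 1-4 s) precedes a 1 s
# auditory cue; reinforcement (water reward / air-puff punishment /
# omission) follows the cue after a 200-400 ms delay according to
# per-cue outcome contingencies. Licking is an inhomogeneous Poisson
# process with an anticipatory ramp between cue and outcome whose slope
# depends on the learned cue value, plus a consummatory bout after
# reward.

#' Session configuration for the Pavlovian conditioning simulator
#'
#' Default contingencies follow the task design: the likely-reward cue
#' (Cue 1) delivers 80% reward / 10% punishment / 10% omission, the
#' likely-punishment cue (Cue 2) 25% reward / 65% punishment / 10%
#' omission. Foreperiods are drawn from an exponential with mean
#' `foreperiod_mean`, truncated to `foreperiod_range` by rejection.
#'
#' @param n_trials number of trials (0 allowed; yields an empty session).
#' @param p_cue1 probability that a trial presents Cue 1.
#' @param contingencies list with elements `cue1` and `cue2`, each a
#'   named probability triplet `c(reward=, punishment=, omission=)`
#'   summing to 1.
#' @param foreperiod_range,foreperiod_mean truncation range (s) and
#'   untruncated mean (s) of the exponential foreperiod.
#' @param delay_range uniform range (s) of the cue-offset-to-outcome
#'   delay.
#' @param cue_duration cue length, seconds.
#' @param iti_quiet required lick-free interval before the next trial,
#'   seconds.
#' @param post_outcome dead time after the outcome before the inter-trial
#'   interval, seconds.
#' @param lick_base baseline anticipatory lick rate at cue onset, Hz.
#' @param lick_learning learning parameter: the anticipatory lick rate
#'   ramps from `lick_base` at cue onset to
#'   `lick_base + lick_learning * value(cue)` at outcome time, where
#'   `value(cue)` is the cue's reward probability. Set 0 for a naive
#'   (non-discriminating) animal.
#' @param consummatory_rate,consummatory_duration lick rate (Hz) and
#'   duration (s) of the post-reward consummatory bout.
#' @param seed integer random seed.
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_trials = 200L,
                           p_cue1 = 0.5,
                           contingencies = list(
                             cue1 = c(reward = 0.80, punishment = 0.10, omission = 0.10),
                             cue2 = c(reward = 0.25, punishment = 0.65, omission = 0.10)),
                           foreperiod_range = c(1, 4),
                           foreperiod_mean = 2,
                           delay_range = c(0.2, 0.4),
                           cue_duration = 1.0,
                           iti_quiet = 1.5,
                           post_outcome = 3.0,
                           lick_base = 0.5,
                           lick_learning = 6,
                           consummatory_rate = 6,
                           consummatory_duration = 1.5,
                           seed = 1L) {
  if (n_trials < 0) stop_config("n_trials must be >= 0")
  if (p_cue1 < 0 || p_cue1 > 1) stop_config("p_cue1 must be a probability")
  if (!is.list(contingencies) || !all(c("cue1", "cue2") %in% names(contingencies)))
    stop_config("contingencies must be a list with elements 'cue1' and 'cue2'")
  for (nm in c("cue1", "cue2")) {
    p <- contingencies[[nm]]
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop_config("contingency triplet '%s' must be 3 non-negative probabilities summing to 1", nm)
    if (is.null(names(p))) names(contingencies[[nm]]) <- c("reward", "punishment", "omission")
  }
  if (foreperiod_range[1] < 0 || foreperiod_range[1] >= foreperiod_range[2])
    stop_config("foreperiod_range must satisfy 0 <= min < max")
  if (foreperiod_mean <= 0) stop_config("foreperiod_mean must be positive")
  if (delay_range[1] < 0 || delay_range[1] > delay_range[2])
    stop_config("delay_range must satisfy 0 <= min <= max")
  structure(list(
    n_trials = as.integer(n_trials), p_cue1 = p_cue1,
    contingencies = contingencies,
    foreperiod_range = foreperiod_range, foreperiod_mean = foreperiod_mean,
    delay_range = delay_range, cue_duration = cue_duration,
    iti_quiet = iti_quiet, post_outcome = post_outcome,
    lick_base = lick_base, lick_learning = lick_learning,
    consummatory_rate = consummatory_rate,
    consummatory_duration = consummatory_duration,
    seed = as.integer(seed)), class = "session_config")
}

# Truncated exponential by rejection; cheap because with the default
# mean 2 s about half of all draws land inside [1, 4].
rtrunc_exp <- function(n, mean, range) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rexp(2L * (n - length(out)) + 8L, rate = 1 / mean)
    out <- c(out, draw[draw >= range[1] & draw <= range[2]])
  }
  out[seq_len(n)]
}

# Inhomogeneous Poisson by thinning with a linear rate ramp on [t0, t1).
rramp_licks <- function(t0, t1, rate0, rate1) {
  rmax <- max(rate0, rate1)
  if (rmax <= 0 || t1 <= t0) return(numeric(0))
  cand <- rpoisson_process(rmax, t0, t1)
  if (length(cand) == 0L) return(cand)
  lambda <- rate0 + (rate1 - rate0) * (cand - t0) / (t1 - t0)
  cand[runif(length(cand)) < lambda / rmax]
}

#' Simulate one Pavlovian conditioning session
#'
#' Generates the per-trial event table and the lick-time series. Each
#' trial draws its randomness from a sub-stream derived from
#' `config$seed` and the trial index, so extending `n_trials` leaves
#' earlier trials unchanged. Foreperiods are lick-free by construction
#' (trial restarts on foreperiod licks are not simulated, as they change
#' no downstream statistic).
#'
#' @param config a [session_config()].
#' @return A list of class `session` with elements
#'   \describe{
#'     \item{trials}{data.frame with columns `trial`, `cue_id`,
#'       `cue_onset`, `foreperiod`, `outcome`, `outcome_time` (`NA` for
#'       omissions).}
#'     \item{licks}{sorted numeric vector of lick times, seconds.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  n <- config$n_trials
  empty <- data.frame(trial = integer(0), cue_id = integer(0),
                      cue_onset = numeric(0), foreperiod = numeric(0),
                      outcome = character(0), outcome_time = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0L)
    return(structure(list(trials = empty, licks = numeric(0), config = config),
                     class = "session"))

  outcomes <- c("reward", "punishment", "omission")
  cue_id <- integer(n); cue_onset <- numeric(n); foreperiod <- numeric(n)
  outcome <- character(n); outcome_time <- numeric(n)
  licks <- vector("list", n)
  t_cursor <- 0

  for (i in seq_len(n)) {
    with_seed(substream_seed(config$seed, i), {
      cue_id[i] <- if (runif(1) < config$p_cue1) 1L else 2L
      foreperiod[i] <- rtrunc_exp(1L, config$foreperiod_mean, config$foreperiod_range)
      cue_onset[i] <- t_cursor + config$iti_quiet + foreperiod[i]
      contingency <- config$contingencies[[cue_id[i]]]
      outcome[i] <- sample(outcomes, 1L, prob = contingency)
      cue_end <- cue_onset[i] + config$cue_duration
      if (outcome[i] == "omission") {
        outcome_time[i] <- NA_real_
        epoch_end <- cue_end + mean(config$delay_range)
      } else {
        outcome_time[i] <- cue_end + runif(1, config$delay_range[1], config$delay_range[2])
        epoch_end <- outcome_time[i]
      }
      # anticipatory licking: linear ramp from cue onset to the (actual
      # or expected) outcome time, slope set by the learned cue value
      value <- unname(config$contingencies[[cue_id[i]]]["reward"])
      r1 <- config$lick_base + config$lick_learning * value
      lk <- rramp_licks(cue_onset[i], epoch_end, config$lick_base, r1)
      if (outcome[i] == "reward")
        lk <- c(lk, rpoisson_process(config$consummatory_rate,
                                     outcome_time[i],
                                     outcome_time[i] + config$consummatory_duration))
      licks[[i]] <- lk
      t_cursor <- epoch_end + config$post_outcome
    })
  }

  trials <- data.frame(trial = seq_len(n), cue_id = cue_id,
                       cue_onset = cue_onset, foreperiod = foreperiod,
                       outcome = outcome, outcome_time = outcome_time,
                       stringsAsFactors = FALSE)
  structure(list(trials = trials,
                 licks = canonical_times(unlist(licks)),
                 config = config),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("Pavlovian session: %d trials, %d licks, duration %.1f s\n",
              nrow(x$trials), length(x$licks),
              if (nrow(x$trials)) max(x$trials$cue_onset) else 0))
  if (nrow(x$trials)) {
    tab <- table(x$trials$cue_id, x$trials$outcome)
    print(tab)
  }
  invisible(x)
}
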