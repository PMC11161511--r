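# Plain-text input/output. All times are written in seconds with six
# decimal places (microsecond resolution).

fmt6 <- function(x) ifelse(is.na(x), NA, sprintf("%.6f", x))

#' Write / read a trial table as CSV
#'
#' Columns: `trial`, `cue_id`, `cue_onset`, `foreperiod`, `outcome`,
#' `outcome_time` (empty for omissions); times in seconds with six
#' decimal places.
#'
#' @param trials trial table data.frame (the `trials` element of a
#'   [generate_session()] result).
#' @param path file path.
#' @return `read_trials()` returns the trial table; `write_trials()`
#'   the path, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  for (col in c("cue_onset", "foreperiod", "outcome_time"))
    out[[col]] <- fmt6(out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("cue_onset", "foreperiod", "outcome_time"))
    df[[col]] <- as.numeric(df[[col]])
  df$trial <- as.integer(df$trial)
  df$cue_id <- as.integer(df$cue_id)
  df
}

#' Write / read an event-time series (licks, spikes, pulses) as CSV
#'
#' One column `time_s`, seconds with six decimal places, sorted.
#'
#' @param times numeric event times, seconds.
#' @param path file path.
#' @return `read_times()` returns a sorted numeric vector;
#'   `write_times()` the path, invisibly.
#' @export
write_times <- function(times, path) {
  write.csv(data.frame(time_s = fmt6(sort(times))), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_times
#' @export
read_times <- function(path) {
  sort(as.numeric(read.csv(path)$time_s))
}

#' Write / read a two-channel photometry recording as CSV
#'
#' Columns `t`, `f465`, `f405`; the sampling rate is recovered from the
#' time stamps on read.
#'
#' @param recording a [photometry_recording()].
#' @param path file path.
#' @return `read_photometry()` returns a `photometry_recording`;
#'   `write_photometry()` the path, invisibly.
#' @export
write_photometry <- function(recording, path) {
  stopifnot(inherits(recording, "photometry_recording"))
  write.csv(data.frame(t = recording$t, f465 = recording$f465,
                       f405 = recording$f405),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_photometry
#' @export
read_photometry <- function(path) {
  df <- read.csv(path)
  fs <- 1 / median(diff(df$t))
  photometry_recording(df$f465, df$f405, fs = fs, t0 = df$t[1])
}
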