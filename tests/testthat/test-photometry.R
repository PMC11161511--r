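test_that("low-pass preserves the passband and rejects the stopband", {
  fs <- 1000
  tt <- seq(0, 10, by = 1 / fs)
  rec <- photometry_recording(10 + sin(2 * pi * 5 * tt),
                              10 + sin(2 * pi * 5 * tt), fs)
  lp <- lowpass(rec)
  mid <- seq(2 * fs, 8 * fs)
  amp <- (max(lp$f465[mid]) - min(lp$f465[mid])) / 2
  expect_lt(abs(amp - 1), 0.01)
  const <- lowpass(photometry_recording(rep(7, 5000), rep(3, 5000), fs))
  expect_equal(const$f465, rep(7, 5000), tolerance = 1e-9)
  rec2 <- photometry_recording(sin(2 * pi * 100 * tt), tt * 0 + 1, fs)
  hp <- lowpass(rec2)
  expect_lt(max(abs(hp$f465[mid])), 0.1)   # > 20 dB down
  expect_error(lowpass(rec, cutoff = 600), "Nyquist")
})

test_that("isosbestic fit solves the normal equations exactly", {
  fit <- fit_isosbestic(c(20, 24, 20, 24), c(10, 12, 10, 12))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  x <- c(1, 2, 3, 4, 5)
  fit2 <- fit_isosbestic(x, x)
  expect_equal(fit2$slope, 1)
  expect_equal(fit2$intercept, 0)
  fit3 <- fit_isosbestic(3 * x - 5, x)
  expect_equal(fit3$slope, 3)
  expect_equal(fit3$intercept, -5)
  expect_error(fit_isosbestic(x, rep(2, 5)), "zero variance")
  fb <- fit_isosbestic(x, rep(2, 5), allow_intercept_only = TRUE)
  expect_equal(fb$f405_fitted, rep(3, 5))
})

test_that("dF/F follows its defining identity", {
  f <- c(100, 101, 99)
  expect_equal(compute_dff(f, f), c(0, 0, 0))
  expect_equal(compute_dff(1.05 * f, f), rep(5, 3))
  expect_error(compute_dff(f, c(100, 0, 99)), "positive")
})

test_that("dF/F is scale-invariant after refitting", {
  set.seed(33)
  f405 <- 100 + rnorm(2000)
  f465 <- 1.2 * f405 + 5 + rnorm(2000, 0, 0.1)
  dff1 <- compute_dff(f465, fit_isosbestic(f465, f405)$f405_fitted)
  dff2 <- compute_dff(3 * f465, fit_isosbestic(3 * f465, 3 * f405)$f405_fitted)
  expect_equal(dff1, dff2, tolerance = 1e-9)
})

test_that("high-pass removes slow drift but keeps fast transients", {
  fs <- 200
  tt <- seq(0, 60, by = 1 / fs)
  expect_equal(mean(highpass(rep(4, length(tt)), fs)), 0, tolerance = 1e-6)
  drift <- sin(2 * pi * 0.01 * tt)
  expect_lt(max(abs(highpass(drift, fs))) / 1, 0.1)
  fast <- sin(2 * pi * 2 * tt)
  hp <- highpass(fast, fs)
  mid <- seq(10 * fs, 50 * fs)
  expect_lt(abs(max(hp[mid]) - 1), 0.05)
  expect_warning(short <- highpass(rep(1, 100), fs), "skipped")
  expect_equal(short, rep(1, 100))
})

test_that("filters are zero-phase: transient peak latency is preserved", {
  fs <- 500
  tt <- seq(0, 20, by = 1 / fs)
  pulse <- exp(-(tt - 10)^2 / (2 * 0.1^2))
  rec <- photometry_recording(100 + pulse, rep(80, length(tt)), fs)
  lp <- lowpass(rec)
  expect_lte(abs(which.max(lp$f465) - which.max(pulse)), 1)
  hp <- highpass(pulse, fs)
  expect_lte(abs(which.max(hp) - which.max(pulse)), 1)
})

test_that("a noiseless proportional recording yields identically zero dF/F", {
  s <- generate_session(session_config(n_trials = 10, p_cue1 = 0, seed = 43))
  prof <- response_profile(gains = c(cue = 1, reward = 1, punishment = 3))
  pc <- photometry_config(noise_sd = 0, motion_amp = 0, gain = 0, seed = 43)
  rec <- generate_photometry(s$trials, prof, pc)
  fit <- fit_isosbestic(rec$f465, rec$f405)
  expect_lt(max(abs(compute_dff(rec$f465, fit$f405_fitted))), 1e-9)
})

test_that("the pipeline recovers an event response and scales with amplitude", {
  s <- generate_session(session_config(n_trials = 60, p_cue1 = 0, seed = 44))
  pun <- s$trials$outcome_time[s$trials$outcome == "punishment"]
  cue <- s$trials$cue_onset[s$trials$outcome == "punishment"]
  peak_for <- function(amp) {
    prof <- response_profile(gains = c(cue = 1, reward = 1,
                                       punishment = 1 + amp))
    rec <- generate_photometry(s$trials, prof,
                               photometry_config(gain = 0.05, seed = 44))
    z <- align_average(process_photometry(rec), pun, window = c(-1, 3),
                       baseline_events = cue)
    max(z$rate[z$bin_centers > 0 & z$bin_centers < 1])
  }
  peaks <- vapply(c(0.5, 1, 2), peak_for, 0)
  expect_gt(peaks[3], 3)
  expect_true(all(diff(peaks) > 0))   # monotone amplitude recovery
})

test_that("align_average flags degenerate baselines and drops edge events", {
  fs <- 200
  x <- list(t = seq(0, 100, by = 1 / fs), dff = rep(0, 20001), fs = fs)
  z <- align_average(x, events = c(10, 50, 99.9), window = c(-1, 2))
  expect_true(z$degenerate)
  expect_true(all(z$rate == 0))
  expect_identical(z$n_events, 2L)    # event at 99.9 falls off the edge
  expect_gte(z$n_dropped, 1)
})
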