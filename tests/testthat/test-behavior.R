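test_that("lick PETH handles delta and empty inputs", {
  events <- seq(10, 100, by = 10)
  licks <- events + 0.5
  p <- lick_peth(licks, events, window = c(0, 1), binsize = 0.001, kernel_sd = 0)
  hit <- which(p$rate > 0)
  expect_length(hit, 1L)
  expect_equal(p$bin_centers[hit], 0.5005)
  expect_equal(p$rate[hit], 1000)
  p0 <- lick_peth(numeric(0), events, window = c(0, 1), kernel_sd = 0)
  expect_true(all(p0$rate == 0))
  expect_error(lick_peth(licks, numeric(0)), "non-empty")
})

test_that("a learner licks more and earlier after the reward cue", {
  s <- generate_session(session_config(n_trials = 300, seed = 41))
  tr <- s$trials
  cue1 <- tr$cue_onset[tr$cue_id == 1]
  cue2 <- tr$cue_onset[tr$cue_id == 2]
  win <- c(0, 1.1)
  p1 <- lick_peth(s$licks, cue1, window = win)
  p2 <- lick_peth(s$licks, cue2, window = win)
  expect_gt(mean(p1$rate), mean(p2$rate))
  a1 <- anticipatory_rate(s$licks, cue1)
  a2 <- anticipatory_rate(s$licks, cue2)
  expect_gt(mean(a1), mean(a2))
  rt1 <- reaction_time(s$licks, cue1)
  rt2 <- reaction_time(s$licks, cue2)
  expect_gt(median(rt2, na.rm = TRUE), median(rt1, na.rm = TRUE))
})

test_that("anticipatory rate and reaction time arithmetic", {
  expect_equal(anticipatory_rate(c(10.7, 11.0), 10), 4)     # 2 licks / 0.5 s
  expect_equal(anticipatory_rate(numeric(0), 10), 0)
  expect_equal(reaction_time(c(10.3, 10.7), 10), 0.3)
  expect_true(is.na(reaction_time(c(15), 10, max_wait = 2)))
  expect_error(reaction_time(1, 0, max_wait = -1), "max_wait")
})

test_that("per-session anticipatory discrimination replicates across sessions", {
  rates <- t(vapply(1:30, function(i) {
    s <- generate_session(session_config(n_trials = 60, seed = 200 + i))
    tr <- s$trials
    c(mean(anticipatory_rate(s$licks, tr$cue_onset[tr$cue_id == 1])),
      mean(anticipatory_rate(s$licks, tr$cue_onset[tr$cue_id == 2])))
  }, numeric(2)))
  p <- suppressWarnings(wilcox.test(rates[, 1], rates[, 2], paired = TRUE,
                                    alternative = "greater"))$p.value
  expect_lt(p, 0.01)
})

test_that("auROC matches exhaustive pair counting and its closed forms", {
  expect_equal(auroc(c(1, 2, 3), c(0, 1, 2)), 7 / 9)
  expect_equal(auroc(c(5, 6), c(1, 2)), 1)
  for (i in 1:40) {
    set.seed(i)
    a <- sample(0:10, sample(2:50, 1), replace = TRUE)
    b <- sample(0:10, sample(2:50, 1), replace = TRUE)
    expect_equal(auroc(a, b), oracle_auroc(a, b))
    if (length(intersect(a, b)) == 0)
      expect_equal(auroc(a, b) + auroc(b, a), 1)
  }
  set.seed(1)
  a <- rnorm(10); b <- rnorm(12)
  expect_equal(auroc(a, b) + auroc(b, a), 1)  # tie-free complement
})

test_that("auROC time-course is calibrated under label exchange", {
  set.seed(7)
  ga <- matrix(rnorm(8 * 20), nrow = 8)
  gb <- matrix(rnorm(8 * 20), nrow = 8)
  tc <- auroc_timecourse(ga, gb, n_resamples = 200, seed = 7)
  expect_true(all(tc$timecourse$auroc >= 0 & tc$timecourse$auroc <= 1))
  expect_true(all(tc$timecourse$p >= tc$p_floor))
  expect_equal(tc$p_floor, 1 / 201)
  expect_lte(mean(tc$timecourse$p < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 20))
  expect_error(auroc_timecourse(ga[1, , drop = FALSE], gb), ">= 2 sessions")
})

test_that("auROC time-course separates a strong group difference", {
  set.seed(8)
  ga <- matrix(rnorm(6 * 10, mean = 3), nrow = 6)
  gb <- matrix(rnorm(6 * 10, mean = 0), nrow = 6)
  tc <- auroc_timecourse(ga, gb, n_resamples = 200, seed = 8)
  expect_true(all(tc$timecourse$auroc > 0.9))
  expect_true(all(tc$timecourse$p < 0.05))
  expect_gte(nrow(tc$spans), 1)
})

test_that("session lick series reflects the learned cue difference", {
  s <- generate_session(session_config(n_trials = 150, seed = 51))
  d <- session_lick_series(s)
  expect_length(d, 110)
  expect_gt(mean(d[60:110]), 0)  # late anticipatory window favors Cue 1
  naive <- generate_session(session_config(n_trials = 150, lick_learning = 0,
                                           seed = 51))
  d0 <- session_lick_series(naive)
  expect_lt(abs(mean(d0[60:110])), abs(mean(d[60:110])))
})
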