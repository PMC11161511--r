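test_that("spike PETH recovers stationary and delta structure", {
  set.seed(61)
  spk <- sort(runif(rpois(1, 10 * 400), 0, 400))
  events <- seq(5, 395, length.out = 200)
  p <- spike_peth(spk, events, window = c(-1, 1), binsize = 0.05, kernel_sd = 0)
  se <- sqrt(10 / (200 * 0.05))
  expect_true(all(abs(p$rate - 10) < 3.5 * se))
  events2 <- seq(10, 100, by = 10)
  p2 <- spike_peth(events2, events2, window = c(-0.5, 0.5), binsize = 0.001,
                   kernel_sd = 0)
  hit <- which(p2$rate > 0)
  expect_length(hit, 1L)
  expect_equal(p2$rate[hit], 1000)
})

test_that("responder PETH peaks near the configured latency", {
  s <- generate_session(session_config(n_trials = 80, p_cue1 = 0, seed = 71))
  prof <- response_profile(baseline_rate = 5,
                           gains = c(cue = 1, reward = 1, punishment = 6),
                           latency = 0.05, jitter = 0.01,
                           response_duration = 0.1)
  st <- generate_spike_train(s$trials, prof, seed = 71)
  pun <- s$trials$outcome_time[s$trials$outcome == "punishment"]
  p <- spike_peth(st, pun, window = c(-0.5, 0.5))
  peak_t <- p$bin_centers[which.max(p$rate)]
  expect_lt(abs(peak_t - (0.05 + 0.05)), 0.1 + 3 * 0.01)
})

test_that("z-scoring normalizes the baseline and flags degeneracy", {
  p <- structure(list(bin_centers = c(-0.75, -0.45, -0.15, 0.25),
                      rate = c(1, 2, 3, 4), n_events = 10L, binsize = 0.3,
                      kernel_sd = 0, baseline_window = NULL,
                      zscored = FALSE, degenerate = FALSE, trials = NULL),
                 class = "peth")
  z <- zscore_peth(p, baseline_window = c(-1, 0))
  expect_equal(z$rate[4], 2)                     # (4 - 2) / 1
  expect_equal(mean(z$rate[1:3]), 0, tolerance = 1e-12)
  expect_equal(sd(z$rate[1:3]), 1, tolerance = 1e-12)
  pc <- p; pc$rate <- rep(5, 4)
  zc <- zscore_peth(pc, c(-1, 0))
  expect_true(zc$degenerate)
  expect_true(all(zc$rate == 0))
  # affine invariance of the z transform
  pa <- p; pa$rate <- 3 * p$rate + 7
  za <- zscore_peth(pa, c(-1, 0))
  expect_equal(za$rate, z$rate, tolerance = 1e-12)
})

test_that("response classification resolves full separations", {
  base_ev <- seq(10, 300, by = 10)
  spk <- sort(c(unlist(lapply(base_ev, function(e) e - runif(5, 0, 1))),
                unlist(lapply(base_ev, function(e) e + runif(10, 0, 0.5)))))
  rc <- classify_response(spk, base_ev)
  expect_identical(rc$direction, "activated")
  expect_lt(rc$p_activation, 1e-6)
  spk2 <- sort(unlist(lapply(base_ev, function(e) e - runif(5, 0, 1))))
  rc2 <- classify_response(spk2, base_ev)
  expect_identical(rc2$direction, "inhibited")
  expect_error(classify_response(spk, base_ev[1:3]), ">= 5 trials")
})

test_that("session-half comparison detects adaptation and handles one unit", {
  events <- seq(5, by = 6, length.out = 60)
  trials <- data.frame(trial = seq_along(events), cue_id = 2L,
                       cue_onset = events - 1.3, foreperiod = 2,
                       outcome = "punishment", outcome_time = events)
  prof <- response_profile(baseline_rate = 8,
                           gains = c(cue = 1, reward = 1, punishment = 6),
                           adaptation = 0.95, response_duration = 0.3)
  pop <- lapply(1:15, function(i)
    list(spikes = generate_spike_train(trials, prof, seed = 300 + i),
         events = events))
  res <- session_half_comparison(pop)
  expect_gt(median(res$units$peak_first - res$units$peak_second), 0)
  expect_lt(res$p_peak, 0.05)
  one <- session_half_comparison(pop[1])
  expect_true(is.na(one$p_peak))
  expect_identical(nrow(one$units), 1L)
})

test_that("autocorrelogram equals brute-force pair enumeration", {
  spk_ms <- c(0, 10, 20, 30) / 1000
  a <- acg(spk_ms, resolution = 5e-4, max_lag = 0.05)
  expect_equal(sum(a$counts), 6)
  near <- function(lag) sum(a$counts[abs(a$lags_ms - lag) < 0.5])
  expect_equal(near(10), 3)
  expect_equal(near(20), 2)
  expect_equal(near(30), 1)
  for (i in 1:25) {
    set.seed(i)
    tt <- sort(runif(sample(5:200, 1), 0, 2))
    expect_equal(acg(tt, max_lag = 0.3)$counts,
                 oracle_acg_counts(tt, 5e-4, 0.3))
  }
  expect_error(acg(0.5), ">= 2 spikes")
})

test_that("surrogate-normalized ACG of a Poisson train is flat", {
  set.seed(9)
  tt <- sort(runif(3000, 0, 150))
  a <- acg(tt, max_lag = 0.25, n_surrogates = 100, seed = 9)
  expect_true(all(abs(a$zcounts) < 4.5))
})

test_that("burst index follows its closed form and bounds", {
  fake <- structure(list(lags_ms = seq(0.25, 199.75, by = 0.5),
                         counts = rep(2, 400), resolution_ms = 0.5,
                         normalized = FALSE), class = "acg")
  fake$counts[10] <- 8                         # lag 4.75 ms
  expect_equal(burst_index(fake), 0.75)        # (8 - 2) / 8
  flat <- fake; flat$counts <- rep(3, 400)
  expect_equal(burst_index(flat), 0)
  zero <- fake; zero$counts <- rep(0, 400)
  expect_equal(burst_index(zero), 0)
  short <- fake; short$lags_ms <- seq(0.25, 99.75, by = 0.5)
  expect_error(burst_index(short), "200")
})

test_that("bursting criterion separates bursty from Poisson units", {
  bursty <- generate_spike_train(NULL,
    response_profile(baseline_rate = 20, burstiness = 0.6),
    duration = 300, seed = 12)
  poisson <- generate_spike_train(NULL,
    response_profile(baseline_rate = 20), duration = 300, seed = 12)
  expect_gt(burst_index(acg(bursty)), 0.3)
  expect_lt(abs(burst_index(acg(poisson))), 0.3)
  expect_true(is_bursting(bursty))
  expect_false(is_bursting(poisson))
})

test_that("burst segmentation applies the ISI rules", {
  seg <- segment_bursts(c(0, 5, 12, 40, 48, 60, 100) / 1000)
  expect_equal(seg$burst_id, c(1L, 1L, 1L, 2L, 2L, 2L, NA))
  expect_equal(seg$bursts$n_spikes, c(3L, 3L))
  seg2 <- segment_bursts(c(0, 12) / 1000)
  expect_true(all(is.na(seg2$burst_id)))
  seg0 <- segment_bursts(numeric(0))
  expect_identical(nrow(seg0$bursts), 0L)
})

test_that("burst segmentation matches the rule oracle on random trains", {
  for (i in 1:200) {
    tt <- random_train(i, duration = 5)
    expect_identical(segment_bursts(tt)$burst_id, oracle_burst_ids(tt))
  }
})

test_that("response clustering recovers archetypes and orders by tagging", {
  sim <- simulate_response_archetypes(n_per = 20, noise_sd = 0.1, seed = 14)
  cl <- cluster_responses(sim$zpeths, k = 5, n_pc = 3, tagged = sim$tagged,
                          seed = 14)
  ari <- mclust::adjustedRandIndex(cl$cluster, sim$labels)
  expect_gte(ari, 0.9)
  expect_true(all(cl$cluster[sim$labels == 1] == 1))
  expect_true(all(diff(cl$tagged_fraction) <= 0))
  expect_error(cluster_responses(sim$zpeths[1:4, ], k = 5), "exceeds")
  ident <- matrix(1, nrow = 10, ncol = 8)
  cli <- cluster_responses(ident, k = 3)
  expect_true(cli$degenerate)
  expect_true(all(cli$cluster == 1L))
})

test_that("quality metrics separate well-isolated from overlapping units", {
  set.seed(15)
  cl <- matrix(rnorm(400), ncol = 2)
  far <- matrix(rnorm(600), ncol = 2)
  far <- far / sqrt(rowSums(far^2)) * 10 + 30        # all ~Mahalanobis 10+
  q <- unit_quality(cl, far)
  expect_gt(q$isolation_distance, 20)
  expect_lt(q$l_ratio, 0.15)
  expect_true(q$pass)
  same <- matrix(rnorm(600), ncol = 2)
  q2 <- unit_quality(cl, same)
  expect_lt(q2$isolation_distance, 20)
  expect_gt(q2$l_ratio, 0.15)
  expect_false(q2$pass)
  const <- matrix(1, nrow = 50, ncol = 2)
  expect_error(unit_quality(const, same), "singular")
})

test_that("duplicate detection respects tetrode, depth and similarity gates", {
  set.seed(16)
  base <- sort(runif(800, 0, 100))
  w <- dnorm(seq(-3, 3, length.out = 32))
  units <- list(
    list(times = base, waveform = w, tetrode = 1L, depth = 1000),
    list(times = base + 1e-4, waveform = w * 1.1, tetrode = 1L, depth = 1050),
    list(times = sort(runif(800, 0, 100)), waveform = rev(w) - w,
         tetrode = 1L, depth = 1010),
    list(times = base, waveform = w, tetrode = 1L, depth = 1350),
    list(times = base, waveform = w, tetrode = 2L, depth = 1000))
  d <- duplicate_units(units)
  expect_identical(d$group[1], d$group[2])           # true duplicate pair
  expect_false(d$group[3] == d$group[1])             # dissimilar waveform
  expect_false(d$group[4] == d$group[1])             # 350 um apart: not compared
  expect_false(d$group[5] == d$group[1])             # different tetrode
  expect_identical(d$n_unique, 4L)
})
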