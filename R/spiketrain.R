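# Single-unit spike-train analyses: PETHs, Mann-Whitney response
# classification, session-half adaptation, autocorrelograms and burst
# metrics, response clustering, cluster-quality gates and duplicate
# detection.

#' Spike PETH
#'
#' [event_peth()] specialized for spike trains, with a 20 ms default
#' smoothing kernel that resolves fast phasic responses.
#'
#' @param spikes a `spike_train` or sorted numeric spike times, seconds.
#' @inheritParams event_peth
#' @return A `peth` object (rate in Hz).
#' @export
spike_peth <- function(spikes, events, window = c(-2, 2), binsize = 0.01,
                       kernel_sd = 0.02, keep_trials = TRUE) {
  event_peth(spike_times(spikes), events, window, binsize, kernel_sd, keep_trials)
}

spike_times <- function(spikes) {
  if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
}

#' Classify a unit's response to an event
#'
#' Compares per-trial firing rates in a baseline window (1 s before the
#' cue of the same trial) against a test window after the event using
#' one-sided Mann-Whitney U tests in both directions. A unit is
#' `activated` if the increase test is significant at `alpha`,
#' `inhibited` if the decrease test is, otherwise `none`. The baseline
#' is always anchored to the cue even when the test event is the
#' reinforcement, via `baseline_events`.
#'
#' @param spikes spike train (object or numeric times).
#' @param events test event times, seconds (>= 5 required).
#' @param baseline_events event times anchoring the baseline window
#'   (default: the test events themselves; pass the trials' cue onsets
#'   when classifying reinforcement responses).
#' @param baseline,test windows in seconds relative to
#'   `baseline_events` / `events`.
#' @param alpha significance level (default 0.001).
#' @return Object of class `response_class` with `direction`,
#'   `p_activation`, `p_inhibition`, `baseline_rate`, `test_rate`.
#' @export
classify_response <- function(spikes, events, baseline_events = events,
                              baseline = c(-1, 0), test = c(0, 0.5),
                              alpha = 0.001) {
  times <- spike_times(spikes)
  events <- events[!is.na(events)]
  baseline_events <- baseline_events[!is.na(baseline_events)]
  if (length(events) < 5L) stop_config("need >= 5 trials to classify a response")
  if (length(baseline_events) != length(events))
    stop_config("baseline_events must match events one-to-one")
  base_rate <- count_in_window(times, baseline_events + baseline[1],
                               baseline_events + baseline[2]) / diff(baseline)
  test_rate <- count_in_window(times, events + test[1],
                               events + test[2]) / diff(test)
  p_act <- suppressWarnings(
    wilcox.test(test_rate, base_rate, alternative = "greater")$p.value)
  p_inh <- suppressWarnings(
    wilcox.test(test_rate, base_rate, alternative = "less")$p.value)
  direction <- if (p_act < alpha) "activated" else if (p_inh < alpha) "inhibited" else "none"
  structure(list(direction = direction, p_activation = p_act,
                 p_inhibition = p_inh, alpha = alpha,
                 baseline_rate = mean(base_rate), test_rate = mean(test_rate),
                 n_trials = length(events)),
            class = "response_class")
}

#' @export
print.response_class <- function(x, ...) {
  cat(sprintf("response: %s (p_act = %.3g, p_inh = %.3g; %.2f -> %.2f Hz, %d trials)\n",
              x$direction, x$p_activation, x$p_inhibition,
              x$baseline_rate, x$test_rate, x$n_trials))
  invisible(x)
}

#' Compare responses between session halves
#'
#' Splits each unit's events at the median event index (the first half
#' receives the extra event when the count is odd), computes the peak of
#' the smoothed PETH in the test window and the mean baseline rate for
#' each half, and tests first-half versus second-half differences across
#' units with two-sided Wilcoxon signed-rank tests. With a single unit
#' only the descriptive per-unit table is returned.
#'
#' @param population list of units, each a list with elements `spikes`
#'   (spike times or `spike_train`) and `events` (event times; >= 4 per
#'   half required).
#' @param window,binsize,kernel_sd PETH parameters.
#' @param test_window window for the peak response, seconds.
#' @param baseline_window window for the baseline rate, seconds.
#' @return List with `units` (data.frame of per-half peak and baseline
#'   rates), `p_peak`, `p_baseline` (NA when < 2 units).
#' @export
session_half_comparison <- function(population, window = c(-1, 1),
                                    binsize = 0.01, kernel_sd = 0.02,
                                    test_window = c(0, 0.5),
                                    baseline_window = c(-1, 0)) {
  stats_one <- function(u) {
    ev <- u$events[!is.na(u$events)]
    n <- length(ev)
    n1 <- ceiling(n / 2)
    if (n1 < 4L || (n - n1) < 4L) stop_config("each unit needs >= 4 events per half")
    halves <- list(ev[seq_len(n1)], ev[(n1 + 1L):n])
    vapply(halves, function(e) {
      p <- spike_peth(u$spikes, e, window, binsize, kernel_sd, keep_trials = FALSE)
      tw <- p$bin_centers >= test_window[1] & p$bin_centers < test_window[2]
      bw <- p$bin_centers >= baseline_window[1] & p$bin_centers < baseline_window[2]
      c(peak = max(p$rate[tw]), baseline = mean(p$rate[bw]))
    }, numeric(2))
  }
  per_unit <- lapply(population, stats_one)
  units <- data.frame(
    unit = seq_along(population),
    peak_first = vapply(per_unit, function(m) m["peak", 1], 0),
    peak_second = vapply(per_unit, function(m) m["peak", 2], 0),
    baseline_first = vapply(per_unit, function(m) m["baseline", 1], 0),
    baseline_second = vapply(per_unit, function(m) m["baseline", 2], 0))
  p_peak <- p_baseline <- NA_real_
  if (length(population) >= 2L) {
    p_peak <- suppressWarnings(
      wilcox.test(units$peak_first, units$peak_second, paired = TRUE)$p.value)
    p_baseline <- suppressWarnings(
      wilcox.test(units$baseline_first, units$baseline_second, paired = TRUE)$p.value)
  }
  list(units = units, p_peak = p_peak, p_baseline = p_baseline)
}

#' Spike-train autocorrelogram
#'
#' Histogram of positive spike-pair lags at sub-millisecond resolution,
#' zero-lag self-pairs excluded. With `n_surrogates > 0` the counts are
#' z-normalized per lag by the mean and SD over ISI-shuffled surrogate
#' trains (which preserve the ISI distribution but destroy serial
#' structure).
#'
#' @param spikes spike train (>= 2 spikes).
#' @param resolution lag bin width, seconds (default 0.5 ms).
#' @param max_lag largest lag, seconds.
#' @param n_surrogates number of ISI-shuffled surrogates for
#'   normalization (0 = raw counts).
#' @param seed seed for the surrogate shuffles.
#' @return Object of class `acg`: `lags_ms` (bin centers, ms), `counts`,
#'   `normalized`, and if normalized also `zcounts`, `surrogate_mean`,
#'   `surrogate_sd`.
#' @export
acg <- function(spikes, resolution = 5e-4, max_lag = 0.5,
                n_surrogates = 0L, seed = 1L) {
  times <- spike_times(spikes)
  if (length(times) < 2L) stop_config("autocorrelogram requires >= 2 spikes")
  n_bins <- as.integer(round(max_lag / resolution))
  counts_of <- function(tt) {
    tt <- sort(tt)
    n <- length(tt)
    out <- integer(n_bins)
    for (k in seq_len(n - 1L)) {
      d <- tt[(1L + k):n] - tt[seq_len(n - k)]
      d <- d[d < max_lag]
      if (length(d) == 0L) break
      b <- pmin(floor(d / resolution) + 1L, n_bins)
      b <- b[d > 0]  # exclude exact zero-lag coincidences
      out <- out + tabulate(b, nbins = n_bins)
    }
    out
  }
  counts <- counts_of(times)
  lags_ms <- (seq_len(n_bins) - 0.5) * resolution * 1000
  res <- structure(list(lags_ms = lags_ms, counts = counts,
                        resolution_ms = resolution * 1000,
                        normalized = FALSE),
                   class = "acg")
  if (n_surrogates > 0L) {
    isi <- diff(times)
    sur <- with_seed(seed, {
      vapply(seq_len(n_surrogates), function(i) {
        counts_of(times[1] + cumsum(c(0, sample(isi))))
      }, integer(n_bins))
    })
    mu <- rowMeans(sur)
    sdv <- apply(sur, 1L, sd)
    res$surrogate_mean <- mu
    res$surrogate_sd <- sdv
    res$zcounts <- ifelse(sdv > 0, (counts - mu) / sdv, 0)
    res$normalized <- TRUE
  }
  res
}

#' Burst index from an autocorrelogram
#'
#' Normalized difference between the maximum autocorrelogram count at
#' 0-10 ms lags and the mean count at 180-200 ms lags, the normalizer
#' being the greater of the two, yielding an index in \[-1, 1\]. Defined
#' as 0 when both terms are 0. Units with index > 0.3 (and a < 2 ms
#' refractory period, see [is_bursting()]) are considered bursting.
#'
#' @param x an [acg()] covering lags to at least 200 ms.
#' @param short_window,long_window lag windows in ms.
#' @return Burst index, dimensionless in \[-1, 1\].
#' @export
burst_index <- function(x, short_window = c(0, 10), long_window = c(180, 200)) {
  stopifnot(inherits(x, "acg"))
  if (max(x$lags_ms) + x$resolution_ms / 2 < long_window[2] - 1e-9)
    stop_config("autocorrelogram must cover lags to >= %g ms", long_window[2])
  short <- x$lags_ms > short_window[1] & x$lags_ms <= short_window[2]
  long <- x$lags_ms >= long_window[1] & x$lags_ms <= long_window[2]
  a <- max(x$counts[short])
  b <- mean(x$counts[long])
  if (a == 0 && b == 0) return(0)
  (a - b) / max(a, b)
}

#' Bursting criterion
#'
#' A unit is considered bursting when its burst index exceeds
#' `bi_threshold` and its refractory period (0.5th percentile of the
#' inter-spike intervals) is below `refractory_ms`.
#'
#' @param spikes spike train.
#' @param acg_obj optional precomputed [acg()]; computed if missing.
#' @param bi_threshold burst-index threshold (default 0.3).
#' @param refractory_ms refractory-period bound in ms (default 2).
#' @param refractory_quantile ISI quantile used as the refractory
#'   period estimate.
#' @return Logical flag with attributes `burst_index` and
#'   `refractory_ms`.
#' @export
is_bursting <- function(spikes, acg_obj = NULL, bi_threshold = 0.3,
                        refractory_ms = 2, refractory_quantile = 0.005) {
  times <- spike_times(spikes)
  if (is.null(acg_obj)) acg_obj <- acg(times)
  bi <- burst_index(acg_obj)
  refr <- unname(quantile(diff(times), refractory_quantile)) * 1000
  structure(bi > bi_threshold && refr < refractory_ms,
            burst_index = bi, refractory_ms = refr)
}

#' Segment a spike train into bursts
#'
#' Left-to-right scan: a burst starts whenever an inter-spike interval
#' is < 10 ms, and subsequent spikes stay in the burst as long as the
#' ISI remains < 15 ms. Bursts and single spikes partition the train.
#'
#' @param spikes sorted spike train.
#' @param start_isi,continue_isi thresholds in seconds (defaults 10 and
#'   15 ms).
#' @return Object of class `burst_segmentation`: `burst_id` (integer per
#'   spike, `NA` for single spikes) and `bursts` (data.frame with
#'   `start`, `end`, `n_spikes`).
#' @export
segment_bursts <- function(spikes, start_isi = 0.010, continue_isi = 0.015) {
  times <- spike_times(spikes)
  n <- length(times)
  burst_id <- rep(NA_integer_, n)
  if (n >= 2L) {
    isi <- diff(times)
    current <- 0L
    in_burst <- FALSE
    for (i in seq_len(n - 1L)) {
      if (!in_burst) {
        if (isi[i] < start_isi) {
          current <- current + 1L
          burst_id[i] <- current
          burst_id[i + 1L] <- current
          in_burst <- TRUE
        }
      } else {
        if (isi[i] < continue_isi) {
          burst_id[i + 1L] <- current
        } else {
          in_burst <- FALSE
        }
      }
    }
  }
  ids <- unique(burst_id[!is.na(burst_id)])
  bursts <- data.frame(
    burst = ids,
    start = vapply(ids, function(b) min(times[which(burst_id == b)]), 0),
    end = vapply(ids, function(b) max(times[which(burst_id == b)]), 0),
    n_spikes = vapply(ids, function(b) sum(burst_id == b, na.rm = TRUE), 0L))
  structure(list(times = times, burst_id = burst_id, bursts = bursts),
            class = "burst_segmentation")
}

#' Cluster z-scored response profiles
#'
#' Principal components are computed on the unit-by-bin matrix of
#' z-scored cue-aligned PETHs (both cues concatenated per unit); K-means
#' with multiple restarts is run on the first `n_pc` components, and the
#' resulting clusters are relabeled in descending order of the fraction
#' of optogenetically tagged units they contain (ties broken by cluster
#' size), so cluster 1 is the most tagged-enriched.
#'
#' @param zpeths numeric matrix, units in rows, PETH bins in columns.
#' @param k number of clusters (default 5).
#' @param n_pc number of principal components used (default 3).
#' @param tagged optional logical vector per unit; when `NULL` clusters
#'   are ordered by size.
#' @param nstart K-means restarts.
#' @param seed integer random seed.
#' @return List of class `response_clusters`: `cluster` (relabeled
#'   integer per unit), `tagged_fraction`, `sizes`, `scores` (PC
#'   scores), `degenerate` flag (fewer distinct profiles than `k`).
#' @export
cluster_responses <- function(zpeths, k = 5L, n_pc = 3L, tagged = NULL,
                              nstart = 50L, seed = 1L) {
  zpeths <- as.matrix(zpeths)
  n_units <- nrow(zpeths)
  if (k > n_units) stop_config("k = %d exceeds the number of units (%d)", k, n_units)
  if (!is.null(tagged) && length(tagged) != n_units)
    stop_config("tagged must have one flag per unit")
  pc <- prcomp(zpeths, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  n_distinct <- nrow(unique(round(scores, 10)))
  degenerate <- n_distinct < k
  if (degenerate) {
    cl <- rep(1L, n_units)
  } else {
    km <- with_seed(seed, kmeans(scores, centers = k, nstart = nstart,
                                 iter.max = 100L))
    cl <- km$cluster
  }
  present <- sort(unique(cl))
  frac <- vapply(present, function(g) {
    if (is.null(tagged)) 0 else mean(tagged[cl == g])
  }, 0)
  sizes <- vapply(present, function(g) sum(cl == g), 0L)
  ord <- present[order(-frac, -sizes, present)]
  relabel <- match(cl, ord)
  structure(list(cluster = relabel,
                 tagged_fraction = frac[order(-frac, -sizes, present)],
                 sizes = sizes[order(-frac, -sizes, present)],
                 scores = scores, k = k, degenerate = degenerate),
            class = "response_clusters")
}

#' Spike-sorting quality: isolation distance and L-ratio
#'
#' Both metrics are computed from the squared Mahalanobis distances of
#' noise (non-cluster) spikes to the cluster, using the cluster's own
#' feature covariance. The isolation distance is the distance of the
#' n-th closest noise spike, where n is the cluster size; the L-ratio is
#' the summed chi-square tail probability of the noise distances divided
#' by the cluster size. Units pass the quality gate with isolation
#' distance > 20 and L-ratio < 0.15.
#'
#' @param cluster_features numeric matrix of the cluster's spikes
#'   (rows) in feature space (e.g., spike amplitude and first waveform
#'   principal component).
#' @param noise_features numeric matrix of non-cluster spikes in the
#'   same features; at least as many rows as the cluster for the
#'   isolation distance.
#' @param id_threshold,lratio_threshold gate thresholds.
#' @return List of class `unit_quality`: `isolation_distance`,
#'   `l_ratio`, `pass`.
#' @export
unit_quality <- function(cluster_features, noise_features,
                         id_threshold = 20, lratio_threshold = 0.15) {
  x <- as.matrix(cluster_features)
  y <- as.matrix(noise_features)
  if (ncol(x) != ncol(y)) stop_config("feature dimensions must match")
  d <- ncol(x)
  if (d < 1L) stop_config("need at least one feature dimension")
  S <- cov(x)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok || !all(is.finite(S)) || abs(det(S)) < 1e-300)
    stop_config("singular cluster covariance; reduce the feature dimension or add spikes")
  d2 <- mahalanobis(y, colMeans(x), S)
  n_cluster <- nrow(x)
  iso <- if (nrow(y) >= n_cluster) sort(d2)[n_cluster] else NA_real_
  lr <- sum(1 - pchisq(d2, df = d)) / n_cluster
  structure(list(isolation_distance = iso, l_ratio = lr,
                 pass = is.finite(iso) && iso > id_threshold && lr < lratio_threshold,
                 n_cluster = n_cluster, n_noise = nrow(y)),
            class = "unit_quality")
}

#' Detect duplicate units across recording sessions
#'
#' Units recorded on the same tetrode within 200 um dorso-ventral
#' distance are candidate duplicates; a candidate pair is flagged when
#' the Pearson correlation of their mean waveforms and the cosine
#' similarity of their autocorrelograms both exceed their thresholds.
#' Flagged pairs are merged into connected components so each putative
#' neuron is counted once.
#'
#' @param units list of units; each a list with `times` (spike times),
#'   `waveform` (numeric mean waveform), `tetrode` (identifier), and
#'   `depth` (um dorso-ventral).
#' @param max_depth_um candidate window on depth difference (default
#'   200).
#' @param waveform_r waveform correlation threshold (default 0.95).
#' @param acg_cosine autocorrelogram cosine-similarity threshold
#'   (default 0.9).
#' @param acg_max_lag lag range used for the ACG comparison, seconds.
#' @return List of class `duplicate_units`: `group` (integer id per
#'   unit; members of one group are putative duplicates), `pairs`
#'   (data.frame of flagged pairs), `n_unique` distinct neurons.
#' @export
duplicate_units <- function(units, max_depth_um = 200, waveform_r = 0.95,
                            acg_cosine = 0.9, acg_max_lag = 0.1) {
  n <- length(units)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  acgs <- vector("list", n)
  get_acg <- function(i) {
    if (is.null(acgs[[i]]))
      acgs[[i]] <<- acg(units[[i]]$times, max_lag = acg_max_lag)$counts
    acgs[[i]]
  }
  cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  pairs <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ui <- units[[i]]; uj <- units[[j]]
    if (!identical(ui$tetrode, uj$tetrode)) next
    if (abs(ui$depth - uj$depth) > max_depth_um) next
    if (is.null(ui$waveform) || is.null(uj$waveform)) {
      warning(sprintf("units %d/%d lack a waveform; pair skipped", i, j))
      next
    }
    r <- suppressWarnings(cor(as.numeric(ui$waveform), as.numeric(uj$waveform)))
    cs <- cosine(get_acg(i), get_acg(j))
    if (is.finite(r) && r >= waveform_r && cs >= acg_cosine) {
      pairs[[length(pairs) + 1L]] <- data.frame(i = i, j = j,
                                                waveform_r = r, acg_cosine = cs)
      parent[find(i)] <- find(j)
    }
  }
  group <- vapply(seq_len(n), find, 0L)
  group <- match(group, unique(group))
  structure(list(group = group,
                 pairs = if (length(pairs)) do.call(rbind, pairs)
                         else data.frame(i = integer(0), j = integer(0),
                                         waveform_r = numeric(0),
                                         acg_cosine = numeric(0)),
                 n_unique = length(unique(group))),
            class = "duplicate_units")
}
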