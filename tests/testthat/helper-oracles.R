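# Independent brute-force oracles, deliberately written with different
# algorithms than the package implementations they check.

# auROC by exhaustive pair counting, ties half-weight.
oracle_auroc <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(b))
}

# Autocorrelogram by full pair enumeration (upper triangle of the
# lag matrix), positive lags only.
oracle_acg_counts <- function(times, resolution, max_lag) {
  n_bins <- round(max_lag / resolution)
  d <- outer(times, times, "-")
  d <- d[upper.tri(d)]
  d <- abs(d)
  d <- d[d > 0 & d < max_lag]
  tabulate(pmin(floor(d / resolution) + 1, n_bins), nbins = n_bins)
}

# Burst-rule oracle: explicit pointer state machine over spike times.
oracle_burst_ids <- function(times, start_isi = 0.010, continue_isi = 0.015) {
  n <- length(times)
  id <- rep(NA_integer_, n)
  if (n < 2) return(id)
  b <- 0L
  i <- 1L
  while (i < n) {
    if (times[i + 1L] - times[i] < start_isi) {
      b <- b + 1L
      id[i] <- b
      j <- i + 1L
      id[j] <- b
      while (j < n && times[j + 1L] - times[j] < continue_isi) {
        j <- j + 1L
        id[j] <- b
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  id
}

# Jensen-Shannon divergence via direct definition as mean KL to the
# midpoint distribution.
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    keep <- a > 0
    sum(a[keep] * log2(a[keep] / b[keep]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# Random spike train spanning Poisson-to-bursty regimes.
random_train <- function(seed, duration = 30) {
  set.seed(seed)
  rate <- runif(1, 5, 40)
  base <- sort(runif(rpois(1, rate * duration), 0, duration))
  burstiness <- runif(1, 0, 0.7)
  if (burstiness > 0 && length(base) > 0) {
    parents <- base[runif(length(base)) < burstiness]
    extra <- unlist(lapply(parents, function(t0)
      t0 + cumsum(runif(sample(1:3, 1), 0.003, 0.008))))
    base <- c(base, extra)
  }
  unique(round(sort(base), 4))
}
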