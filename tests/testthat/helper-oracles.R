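# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (full rescans, O(n^2) definitions) and
# share no code with the streaming implementations they check.

# mean RR over intervals stamped in [at - w, at), by explicit filtering
brute_trailing_mean <- function(series, at, w) {
  keep <- series$beat_time >= at - w & series$beat_time < at
  if (!any(keep)) NA_real_ else mean(series$rr[keep])
}

# Fixed-threshold oracle: at each beat, rescan backwards for the current
# run of intervals above u0 and re-evaluate duration + confirmation.
oracle_fixed_levels <- function(series, U0, U1, min_dur = 4, min_occ = 2) {
  rr <- series$rr
  n <- length(rr)
  level <- integer(n)
  for (k in seq_len(n)) {
    if (rr[k] <= U0) next
    start <- k
    while (start > 1 && rr[start - 1] > U0) start <- start - 1
    run <- rr[start:k]
    if (sum(run) / 1000 > min_dur && sum(run > U1) >= min_occ) level[k] <- 1L
  }
  level
}

# Adaptive oracle: per-beat threshold recomputed by brute-force window
# filtering; disarmed beats break runs.
oracle_adaptive_levels <- function(series, factor = 1.33, mean_window = 20,
                                   U1 = 800, min_dur = 4, min_occ = 2,
                                   warmup = mean_window) {
  rr <- series$rr
  t <- series$beat_time
  n <- length(rr)
  above <- logical(n)
  for (k in seq_len(n)) {
    mu <- brute_trailing_mean(series, t[k], mean_window)
    armed <- !is.na(mu) && t[k] >= t[1] + warmup
    above[k] <- armed && rr[k] > factor * mu
  }
  level <- integer(n)
  for (k in seq_len(n)) {
    if (!above[k]) next
    start <- k
    while (start > 1 && above[start - 1]) start <- start - 1
    run <- rr[start:k]
    if (sum(run) / 1000 > min_dur && sum(run > U1) >= min_occ) level[k] <- 1L
  }
  level
}

# Page-Hinkley oracle, from the direct definition: within the current armed
# segment [a..n], alarm at n iff max over t in [a..n] of
# sum_{k=t..n} (RR(k) - RR0bar(k) - nu/2) >= lambda (the max over the start
# index equals Lambda_n - m_n). Alarm latches until RR < RR0bar + nu/2.
oracle_ph <- function(series, baseline_window = 290, lambda = 717, nu = 415) {
  rr <- series$rr
  t <- series$beat_time
  n <- length(rr)
  inc <- numeric(n)
  bmean <- numeric(n)
  for (k in seq_len(n)) {
    mu <- brute_trailing_mean(series, t[k], baseline_window)
    bmean[k] <- if (is.na(mu)) rr[k] else mu
    inc[k] <- rr[k] - bmean[k] - nu / 2
  }
  level <- integer(n)
  stat <- rep(NA_real_, n)
  a <- 1L
  alarmed <- FALSE
  k <- 1L
  while (k <= n) {
    if (alarmed) {
      if (rr[k] < bmean[k] + nu / 2) {
        alarmed <- FALSE
        a <- k  # this beat re-enters accumulation
      } else {
        level[k] <- 1L
        k <- k + 1L
        next
      }
    }
    # Lambda_n(t) for every candidate start t in [a..k], by suffix sums
    lam_t <- rev(cumsum(rev(inc[a:k])))
    stat[k] <- max(max(lam_t), 0)  # running minimum includes the empty prefix
    if (stat[k] >= lambda) {
      level[k] <- 1L
      alarmed <- TRUE
      a <- k + 1L
    }
    k <- k + 1L
  }
  list(level = level, stat = stat)
}

# Brute-force matcher, re-deriving the TP/FP/FN assignment rule by rule.
oracle_match <- function(onsets, dets, pre = 5, post = 30, latency = 0) {
  d <- dets + latency
  used_ann <- rep(FALSE, length(onsets))
  dead_ann <- rep(FALSE, length(onsets))
  status <- character(length(d))
  tp_delay <- numeric(0)
  for (i in seq_along(d)) {
    wins <- which(d[i] >= onsets - pre & d[i] <= onsets + post)
    if (length(wins) == 0) {
      status[i] <- "fp"
    } else if (any(!used_ann[wins] & !dead_ann[wins])) {
      a <- wins[!used_ann[wins] & !dead_ann[wins]][1]
      used_ann[a] <- TRUE
      tp_delay <- c(tp_delay, d[i] - onsets[a])
      status[i] <- "tp"
      dead_ann[setdiff(wins, a)] <- TRUE
    } else {
      status[i] <- "ignored"
    }
  }
  list(n_tp = sum(status == "tp"),
       n_fp = sum(status == "fp"),
       n_ignored = sum(status == "ignored"),
       n_fn = sum(!used_ann & !dead_ann),
       delays = tp_delay)
}

# Random RR series with occasional upward mean shifts (bradycardia-like
# plateaus), exercising run logic, window boundaries and PH excursions.
random_rr_series <- function(n_beats = 200, seed = 1) {
  set.seed(seed)
  base <- runif(1, 340, 480)
  rr <- base + rnorm(n_beats, 0, runif(1, 3, 15))
  n_jump <- rpois(1, 2)
  for (j in seq_len(n_jump)) {
    len <- sample(3:25, 1)
    at <- sample(seq_len(max(1, n_beats - len)), 1)
    high <- runif(1, 600, 950)
    rr[at:(at + len - 1)] <- high + rnorm(len, 0, 10)
  }
  rr <- pmax(rr, 260)
  rr_series(beat_time = cumsum(rr) / 1000, rr = rr)
}

# Exact logistic sampler for sigmoid-fit tests
sample_sigmoid_series <- function(A, B, t0, s, from, to, spacing = 0.45,
                                  noise_sd = 0) {
  t <- seq(from, to, by = spacing)
  y <- A + B / (1 + exp(-(t - t0) / s)) + rnorm(length(t), 0, noise_sd)
  rr_series(beat_time = t, rr = y)
}
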