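make_series <- function(rr) rr_series(cumsum(rr) / 1000, rr)

test_that("fixed-threshold detector fires after 4 s of confirmed long intervals", {
  s <- make_series(c(rep(500, 20), rep(810, 10)))
  tr <- detect_fixed(s, fixed_params(U0 = 750, U1 = 800))
  # cumulative above-threshold duration exceeds 4 s at the 5th 810 ms beat
  expect_equal(detections(tr), s$beat_time[25])
  expect_equal(sum(tr$level[1:24]), 0)

  # above U0 forever but never above U1: confirmation clause blocks the alarm
  s2 <- make_series(rep(760, 200))
  expect_length(detections(detect_fixed(s2, fixed_params(750, 800))), 0)

  s3 <- make_series(rep(500, 100))
  expect_length(detections(detect_fixed(s3, fixed_params(750, 800))), 0)
})

test_that("alarm level releases at the first interval back at/below threshold", {
  s <- make_series(c(rep(500, 10), rep(810, 8), rep(500, 5), rep(810, 8)))
  tr <- detect_fixed(s, fixed_params(750, 800))
  # two separate runs, each alarms once; level drops during recovery
  expect_length(detections(tr), 2)
  expect_equal(tr$level[19:23], rep(0L, 5))
})

test_that("adaptive detector tracks the basal rate", {
  # 160 bpm baseline for 60 s, then sudden 810 ms intervals
  s <- make_series(c(rep(375, 160), rep(810, 20)))
  tr <- detect_adaptive(s, adaptive_params(U1 = 800))
  expect_equal(detections(tr), s$beat_time[165])  # 5th post-change beat

  # constant series at any rate: RR = mean < 1.33 * mean, never fires
  for (rr0 in c(300, 400, 550)) {
    expect_length(detections(detect_adaptive(make_series(rep(rr0, 300)),
                                             adaptive_params())), 0)
  }

  # slow drift: +0.5 ms per beat over 10 min stays under the moving threshold
  rr_d <- 375 + 0.5 * seq_len(1300)
  expect_length(detections(detect_adaptive(make_series(rr_d),
                                           adaptive_params(U1 = 800))), 0)
})

test_that("Page-Hinkley statistic accumulates mean shifts and resets", {
  # stationary series: increments are negative, statistic pinned at 0
  s <- make_series(rep(400, 800))
  tr <- detect_page_hinkley(s, ph_params())
  expect_length(detections(tr), 0)
  expect_true(all(attr(tr, "ph_stat") == 0))

  # step 400 -> 1000 ms: increment ~392.5/beat, alarm at the 2nd post-step
  # beat (cumulative ~785 >= 717)
  s2 <- make_series(c(rep(400, 700), rep(1000, 10)))
  tr2 <- detect_page_hinkley(s2, ph_params())
  expect_equal(detections(tr2)[1], s2$beat_time[702])

  # step of exactly nu/2 above baseline: zero increments, never alarms
  s3 <- make_series(c(rep(400, 700), rep(400 + 415 / 2, 50)))
  # freeze the baseline contribution: shift is within the window's reach,
  # so increments stay <= 0 and the statistic cannot build up
  expect_length(detections(detect_page_hinkley(s3, ph_params())), 0)
})

test_that("streaming detectors equal brute-force offline oracles", {
  for (seed in 1:15) {
    s <- random_rr_series(150, seed = seed)
    expect_equal(detect_fixed(s, fixed_params(750, 800))$level,
                 oracle_fixed_levels(s, 750, 800), info = paste("seed", seed))
    expect_equal(detect_adaptive(s, adaptive_params(U1 = 800))$level,
                 oracle_adaptive_levels(s), info = paste("seed", seed))
    expect_equal(detect_page_hinkley(s, ph_params())$level,
                 oracle_ph(s)$level, info = paste("seed", seed))
  }
})

test_that("raising thresholds never yields an earlier detection", {
  first_det <- function(tr) {
    d <- detections(tr)
    if (length(d)) d[1] else Inf
  }
  for (seed in 1:8) {
    s <- random_rr_series(250, seed = seed + 100)
    d_lo <- first_det(detect_fixed(s, fixed_params(600, 640)))
    d_hi <- first_det(detect_fixed(s, fixed_params(750, 800)))
    expect_true(d_hi >= d_lo)
    p_lo <- first_det(detect_page_hinkley(s, ph_params(lambda = 400)))
    p_hi <- first_det(detect_page_hinkley(s, ph_params(lambda = 717)))
    expect_true(p_hi >= p_lo)
  }
})

test_that("detectors are causal: truncation preserves past levels", {
  s <- random_rr_series(200, seed = 77)
  cut <- 120
  s_cut <- rr_series(s$beat_time[1:cut], s$rr[1:cut])
  for (f in list(function(x) detect_fixed(x, fixed_params(750, 800)),
                 function(x) detect_adaptive(x, adaptive_params(U1 = 800)),
                 function(x) detect_page_hinkley(x, ph_params()))) {
    expect_equal(f(s)$level[1:cut], f(s_cut)$level)
  }
})

test_that("detector_config carries the published operating points", {
  y <- detector_config("yellow")
  r <- detector_config("red")
  expect_equal(c(y$fixed$U0, y$fixed$U1), c(600, 640))
  expect_equal(c(r$fixed$U0, r$fixed$U1), c(750, 800))
  expect_equal(y$adaptive$factor, 1.33)
  expect_equal(c(r$ph$baseline_window, r$ph$lambda, r$ph$nu), c(290, 717, 415))
})
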