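rules0 <- match_rules(latency_compensation = 0)

test_that("matching applies the [-5, +30] s window and dedup rules", {
  # detection 3 s before the onset: TP with negative delay
  m <- match_detections(100, 97, rules0)
  expect_equal(nrow(m$tp), 1)
  expect_equal(m$tp$delay, -3)

  # detection 31 s after the onset: outside the window, FP
  m2 <- match_detections(100, 131, rules0)
  expect_equal(m2$fp, 131)
  expect_equal(m2$fn, 100)

  # two detections in one window: first is the TP, second ignored (not FP)
  m3 <- match_detections(100, c(98, 105), rules0)
  expect_equal(m3$tp$detection, 98)
  expect_equal(m3$ignored_detections, 105)
  expect_length(m3$fp, 0)

  # one detection covering two annotations: one TP, second annotation
  # ignored (not FN)
  m4 <- match_detections(c(100, 110), 108, rules0)
  expect_equal(nrow(m4$tp), 1)
  expect_equal(m4$tp$onset, 100)
  expect_equal(m4$ignored_annotations, 110)
  expect_length(m4$fn, 0)

  expect_error(match_detections(c(110, 100), 108, rules0), "sorted")
})

test_that("matching equals a brute-force matcher on random inputs", {
  set.seed(21)
  for (rep_ in 1:40) {
    onsets <- sort(runif(sample(0:12, 1), 0, 600))
    dets <- sort(runif(sample(0:20, 1), -10, 640))
    lat <- sample(c(0, 1.512), 1)
    m <- match_detections(onsets, dets,
                          match_rules(latency_compensation = lat))
    o <- oracle_match(onsets, dets, latency = lat)
    expect_equal(nrow(m$tp), o$n_tp)
    expect_equal(length(m$fp), o$n_fp)
    expect_equal(length(m$fn), o$n_fn)
    expect_equal(length(m$ignored_detections), o$n_ignored)
    expect_equal(sort(m$tp$delay), sort(o$delays), tolerance = 1e-12)
  }
})

test_that("latency compensation shifts delays exactly and FPs stay local", {
  onsets <- c(100, 200, 300)
  dets <- c(101, 203, 306)
  m0 <- match_detections(onsets, dets, rules0)
  m1 <- match_detections(onsets, dets,
                         match_rules(latency_compensation = 1.512))
  expect_equal(m1$tp$delay, m0$tp$delay + 1.512)

  # adding one detection far from every window adds exactly one FP
  m2 <- match_detections(onsets, sort(c(dets, 500)), rules0)
  expect_equal(length(m2$fp), length(m0$fp) + 1)
  expect_equal(m2$tp, m0$tp)
  expect_equal(m2$fn, m0$fn)
})

test_that("metrics compute sensitivity, FAR and delay moments", {
  # TP=2, FP=1, FN=1
  m <- match_detections(c(100, 200, 300), c(99, 203, 450), rules0)
  rep_ <- detection_metrics(m)
  expect_equal(rep_$n_tp, 2)
  expect_equal(rep_$sensitivity, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(rep_$false_alarm_rate, 100 * 1 / 3, tolerance = 1e-9)
  expect_equal(rep_$delay_mean, 1)
  expect_equal(rep_$delay_sd, sd(c(-1, 3)))

  # no FPs -> FAR 0; no events -> undefined markers
  expect_equal(detection_metrics(match_detections(100, 99, rules0))$false_alarm_rate, 0)
  empty <- detection_metrics(match_detections(numeric(0), numeric(0), rules0))
  expect_true(is.na(empty$sensitivity))
  expect_true(is.na(empty$false_alarm_rate))
})

test_that("paired delay comparison behaves under shift, identity and null", {
  a <- c(rnorm(30, 10, 2))
  cmp <- compare_delays(a, a + 3)
  expect_lt(cmp$p_value, 0.001)
  expect_true(compare_delays(a, a)$degenerate)

  # type-I error of the two-sided test is close to nominal 5%
  set.seed(33)
  rej <- replicate(1000, {
    x <- rnorm(20); y <- rnorm(20)
    compare_delays(x, y)$p_value < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("benchmark pools records and degenerates to self-comparison", {
  cfg <- cohort_config(n_records = 3, record_duration = 600, event_rate = 12,
                       seed = 5)
  coh <- simulate_cohort(cfg)
  fixed_fn <- function(s) detect_fixed(s, detector_config("red")$fixed)
  b <- benchmark(coh, list(monitor = list(fn = fixed_fn),
                           clone = list(fn = fixed_fn)),
                 definition = "B80_10")
  expect_equal(b$table$sensitivity[1], b$table$sensitivity[2])
  expect_equal(b$table$delay_mean[1], b$table$delay_mean[2])
  expect_true(b$paired$n_common[1] == b$table$n_tp[1])
  expect_true(is.na(b$paired$p_value[1]))  # identical delays -> degenerate

  expect_error(benchmark(structure(list(records = list(),
                                        config = cfg),
                                   class = "brady_cohort"),
                         list(monitor = list(fn = fixed_fn))),
               "empty cohort")
})
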