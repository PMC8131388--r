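test_that("baseline generation is deterministic and respects its targets", {
  a <- simulate_baseline(300, 155, 10, seed = 4)
  b <- simulate_baseline(300, 155, 10, seed = 4)
  expect_identical(a, b)

  # zero noise, no modulation: constant RR at 60000/hr
  c0 <- simulate_baseline(60, 150, rr_noise_sd = 0)
  expect_true(all(c0$rr == 400))

  # 10-minute mean HR within 2 bpm of the target
  long <- simulate_baseline(600, 160, 10, seed = 8)
  expect_lt(abs(60000 / mean(long$rr) - 160), 2)

  # periodic breathing modulates but stays far above 100 bpm
  pb <- simulate_baseline(300, 150, 5, periodic_breathing = TRUE, seed = 2)
  expect_gt(min(60000 / pb$rr), 110)
  expect_equal(nrow(find_events(pb, brady_definition("B100_5"))), 0)
})

test_that("injected events satisfy the definitions they are built for", {
  base <- simulate_baseline(300, 150, 8, seed = 10)
  # deep 12 s event: severe under both definitions
  deep <- inject_event(base, 120, nadir = 70, duration = 14, n_phases = 1)
  expect_true(deep$truth$B80_10)
  e80 <- find_events(deep$series, brady_definition("B80_10"))
  expect_equal(nrow(e80), 1)

  # shallow 8 s event: yellow-tier only
  shallow <- inject_event(base, 120, nadir = 90, duration = 8)
  expect_false(shallow$truth$B80_10)
  expect_true(shallow$truth$B100_5)
  expect_equal(nrow(find_events(shallow$series,
                                brady_definition("B80_10"))), 0)
  expect_equal(nrow(find_events(shallow$series,
                                brady_definition("B100_5"))), 1)

  # biphasic: one merged event with two phases
  set.seed(6)
  bi <- inject_event(base, 120, nadir = 70, duration = 16, n_phases = 2)
  fe <- find_events(bi$series, brady_definition("B100_5"), merge_gap = 10)
  expect_equal(nrow(fe), 1)
  expect_equal(fe$n_phases, 2)
  expect_equal(bi$truth$n_phases, 2)

  # overlap with an existing event is rejected
  expect_error(inject_event(bi$series, 128, 70, 12), "overlap")
  # events must fit inside the record
  expect_error(inject_event(base, 2, 70, 12), "too close|fit")
})

test_that("ground-truth onsets agree with beat-level event extraction", {
  for (seed in c(3, 12, 31)) {
    rec <- simulate_record(cohort_config(record_duration = 900,
                                         event_rate = 10, seed = seed),
                           seed = seed)
    ev <- find_events(rec$rr, brady_definition("B100_5"))
    expect_equal(nrow(ev), nrow(rec$truth))
    if (nrow(ev)) {
      max_rr <- max(rec$rr$rr) / 1000
      expect_true(all(abs(ev$onset_raw - rec$truth$onset_raw) <= max_rr))
      expect_true(all(abs(ev$offset_raw - rec$truth$offset_raw) <= max_rr))
      expect_equal(ev$n_phases, rec$truth$n_phases)
      # realized nadir within 2 bpm of the nominal one
      expect_true(all(abs(ev$min_hr - rec$truth$min_hr) <= 2))
    }
  }
})

test_that("SpO2 couples desaturations to flagged events only", {
  set.seed(3)
  ev <- data.frame(onset_raw = c(60, 160), offset_raw = c(80, 175),
                   desat = c(TRUE, FALSE))
  spo2 <- simulate_spo2(260, ev, depth = 15, baseline = 97)
  during1 <- spo2$spo2[spo2$time_s >= 55 & spo2$time_s <= 85]
  during2 <- spo2$spo2[spo2$time_s >= 158 & spo2$time_s <= 177]
  expect_lt(min(during1), 97 - 10)
  expect_gt(min(during2), 97 - 5)
  # desaturation begins before the bradycardia onset
  below <- spo2$time_s[spo2$spo2 < 97 - 5]
  expect_lt(min(below), 60)
})

test_that("cohort generation is reproducible and event counts are Poisson-like", {
  cfg <- cohort_config(n_records = 4, record_duration = 600, seed = 9)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$records[[3]]$rr, c2$records[[3]]$rr)
  expect_identical(c1$records[[2]]$truth, c2$records[[2]]$truth)

  counts <- vapply(c1$records, function(r) nrow(r$truth), integer(1))
  lam <- cfg$event_rate * cfg$record_duration / 3600
  expect_lt(abs(sum(counts) - length(counts) * lam),
            3 * sqrt(length(counts) * lam) + 3)
})

test_that("morphology mix is realized at the configured fractions", {
  cfg <- cohort_config(n_records = 80, record_duration = 900,
                       event_rate = 24, duration_range = c(10, 14),
                       artifact_rate = 0, seed = 13)
  coh <- simulate_cohort(cfg)
  phases <- unlist(lapply(coh$records, function(r) r$truth$n_phases))
  expect_gt(length(phases), 250)
  frac <- tabulate(phases, 3) / length(phases)
  expect_true(all(abs(frac - cfg$morphology_mix) < 0.07))
})

test_that("context flags follow the coupling rules", {
  cfg <- cohort_config(n_records = 6, record_duration = 600, event_rate = 12,
                       seed = 17)
  coh <- simulate_cohort(cfg)
  truth <- do.call(rbind, lapply(coh$records, `[[`, "truth"))
  expect_true(all(truth$desat[truth$min_hr < 80]))
  expect_true(all(truth$spo2_drop[truth$desat] >= 10))
  expect_true(all(truth$spo2_drop[!truth$desat] == 0))
})
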