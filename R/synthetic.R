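#' Synthetic cohort configuration
#'
#' Parameters of the seeded preterm-infant record generator. Defaults
#' emulate the monitoring conditions the detectors are designed for: a
#' basal heart rate of 155 +/- 10 bpm across infants, beat-to-beat RR
#' variability of ~10 ms, severe bradycardia events (nadir 55-75 bpm,
#' 15-25 s below 100 bpm) at about 6 per hour, a 66/24/10 percent
#' mono/bi/triphasic morphology mix (about a third of observed events are
#' multiphasic), occasional sensor artifacts, and periodic-breathing HR
#' oscillations in a subset of records.
#'
#' @param n_records number of records.
#' @param record_duration seconds per record.
#' @param baseline_hr_mean,baseline_hr_sd bpm; basal HR distribution across
#'   records.
#' @param rr_noise_sd ms; stationary sd of the AR(1) beat-to-beat RR noise.
#' @param event_rate injected bradycardia events per hour.
#' @param morphology_mix length-3 probabilities (mono, bi, tri), summing to 1.
#' @param depth_range bpm; range of event nadir HR.
#' @param duration_range seconds; range of total time below 100 bpm per event.
#' @param artifact_rate beat-detection artifacts per hour (half missed
#'   beats, half spurious beats).
#' @param periodic_breathing_prob probability that a record carries
#'   periodic-breathing HR oscillations.
#' @param desat_prob probability that a shallow (nadir >= 80 bpm) event is
#'   accompanied by apnea and desaturation; deep events always are.
#' @param seed master seed for the cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_records = 50, record_duration = 1200,
                          baseline_hr_mean = 155, baseline_hr_sd = 10,
                          rr_noise_sd = 10, event_rate = 6,
                          morphology_mix = c(mono = 0.66, bi = 0.24,
                                             tri = 0.10),
                          depth_range = c(55, 75),
                          duration_range = c(15, 25),
                          artifact_rate = 5,
                          periodic_breathing_prob = 0.3,
                          desat_prob = 0.5,
                          seed = 1L) {
  stopifnot(n_records >= 1, record_duration >= 300, baseline_hr_mean > 0,
            baseline_hr_sd >= 0, rr_noise_sd >= 0, event_rate >= 0,
            length(morphology_mix) == 3,
            abs(sum(morphology_mix) - 1) < 1e-9,
            length(depth_range) == 2, length(duration_range) == 2,
            artifact_rate >= 0, periodic_breathing_prob >= 0,
            periodic_breathing_prob <= 1, desat_prob >= 0, desat_prob <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a baseline (event-free) RR series
#'
#' Beats are generated sequentially: RR(k) = 60000/hr(t) plus AR(1) noise
#' (coefficient 0.8, stationary sd `rr_noise_sd`), clipped to [250, 600]
#' ms. With `periodic_breathing = TRUE` the instantaneous HR is modulated
#' by a sinusoid (period 10-15 s, amplitude 5-15 bpm), emulating the
#' benign oscillations of periodic breathing.
#'
#' @param duration record length, seconds.
#' @param baseline_hr basal heart rate, bpm.
#' @param rr_noise_sd ms.
#' @param periodic_breathing logical.
#' @param pb_period,pb_amplitude sinusoid period (s) and HR amplitude
#'   (bpm); drawn uniformly from 10-15 s / 5-15 bpm when `NULL`.
#' @param seed optional; when given, seeds the generator for a
#'   reproducible series.
#' @return An [rr_series()].
#' @export
simulate_baseline <- function(duration, baseline_hr = 155, rr_noise_sd = 10,
                              periodic_breathing = FALSE, pb_period = NULL,
                              pb_amplitude = NULL, seed = NULL) {
  stopifnot(duration > 0, baseline_hr > 0, rr_noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (periodic_breathing) {
    if (is.null(pb_period)) pb_period <- stats::runif(1, 10, 15)
    if (is.null(pb_amplitude)) pb_amplitude <- stats::runif(1, 5, 15)
    pb_phase <- stats::runif(1, 0, 2 * pi)
  }
  n_max <- ceiling(duration / 0.25) + 2L
  noise <- if (rr_noise_sd > 0) {
    innov <- stats::rnorm(n_max, 0, rr_noise_sd * sqrt(1 - 0.8^2))
    as.numeric(stats::filter(innov, 0.8, method = "recursive"))
  } else {
    numeric(n_max)
  }
  times <- numeric(n_max + 1L)
  rr <- numeric(n_max)
  t <- 0
  k <- 0L
  while (t < duration && k < n_max) {
    k <- k + 1L
    hr <- baseline_hr
    if (periodic_breathing) {
      hr <- hr + pb_amplitude * sin(2 * pi * t / pb_period + pb_phase)
    }
    rr[k] <- min(600, max(250, 60000 / hr + noise[k]))
    t <- t + rr[k] / 1000
    times[k + 1L] <- t
  }
  rr_series(beat_time = times[2:(k + 1L)], rr = rr[seq_len(k)])
}

# Double-logistic event profile: target RR (ms) at local time tau (s from
# the nominal start of the first sub-100 bpm phase). Each phase p occupies
# [a_p, b_p]; rr rises from rr_base toward rr_nadir and back with time
# scale s.
event_profile <- function(tau, rr_base, rr_nadir, phases, s) {
  sig <- function(x) 1 / (1 + exp(-x))
  bump <- 0
  for (p in seq_len(nrow(phases))) {
    bump <- bump + sig((tau - phases[p, 1]) / s) * sig((phases[p, 2] - tau) / s)
  }
  rr_base + (rr_nadir - rr_base) * pmin(bump, 1)
}

# Nominal sub-100 phase spans for a morphology: matrix with columns a, b on
# the local tau axis (phase 1 starts at 0). Gaps between phases are drawn
# from 4-8 s (short enough to be merged into one multiphasic event).
morphology_phases <- function(duration, n_phases) {
  frac <- switch(n_phases, 1, c(0.6, 0.4), c(0.5, 0.3, 0.2))
  d <- pmax(duration * frac, 4)
  gaps <- if (n_phases > 1) stats::runif(n_phases - 1, 4, 8) else numeric(0)
  a <- cumsum(c(0, d[-n_phases] + gaps))
  cbind(a = a, b = a + d)
}

#' Inject a bradycardia event into an RR series
#'
#' Replaces the beats around `at` with beats following a sigmoid descent
#' to the nadir, a plateau, and a sigmoid recovery (multiphasic events
#' insert 4-8 s supra-100 bpm recoveries between phases), and returns the
#' ground-truth annotation computed analytically from the continuous
#' profile (independently of the realized beat quantization): the 100 bpm
#' threshold-crossing onset/offset, the severe-definition status, and the
#' true sigmoid-adjusted onset (first point where the profile's derivative
#' exceeds 1 ms/s).
#'
#' @param series an [rr_series()] (typically from [simulate_baseline()]).
#' @param at seconds; nominal start of the first sub-100 bpm phase.
#' @param nadir bpm; event nadir HR, below the series' baseline.
#' @param duration seconds; total nominal time below 100 bpm (split across
#'   phases for multiphasic morphologies).
#' @param n_phases 1 (mono), 2 (bi) or 3 (triphasic).
#' @param transition_s sigmoid time scale of the descents/recoveries, s.
#' @return A list: `series` (the modified [rr_series()]) and `truth` (a
#'   one-row data.frame with `onset_raw`, `offset_raw`, `duration`,
#'   `n_phases`, `min_hr`, `onset_adj_true`, `B100_5`, `B80_10`).
#' @export
inject_event <- function(series, at, nadir, duration, n_phases = 1,
                         transition_s = 0.8) {
  stopifnot(inherits(series, "rr_series"), n_phases %in% 1:3,
            duration > 6, nadir > 0)
  t <- series$beat_time
  rr_nadir <- 60000 / nadir
  pre <- series$rr[t >= at - 10 & t < at]
  if (length(pre) < 5) stop("event does not fit: too close to record start")
  rr_base <- stats::median(pre)
  if (rr_nadir <= rr_base + 50) {
    stop("event nadir must be well below the baseline heart rate")
  }
  phases <- morphology_phases(duration, n_phases)
  s <- transition_s
  lead <- 8 * s + 2
  tail_ <- 8 * s + 2
  span <- c(at - lead, at + phases[n_phases, 2] + tail_)
  if (span[1] <= t[1] + 1 || span[2] >= t[length(t)] - 1) {
    stop("event does not fit inside the record")
  }
  spans <- attr(series, "injected_spans")
  if (!is.null(spans) &&
      any(spans[, 1] < span[2] + 15 & spans[, 2] > span[1] - 15)) {
    stop("event overlaps a previously injected event")
  }

  prof <- function(tt) event_profile(tt - at, rr_base, rr_nadir, phases, s)

  # --- splice beats: keep originals before the span, generate through it
  keep_pre <- which(t < span[1])
  t_cur <- t[keep_pre[length(keep_pre)]]
  gen_t <- numeric(0)
  gen_rr <- numeric(0)
  while (t_cur < span[2]) {
    rr_k <- prof(t_cur)
    t_cur <- t_cur + rr_k / 1000
    gen_t <- c(gen_t, t_cur)
    gen_rr <- c(gen_rr, rr_k)
  }
  post_idx <- which(t >= t_cur + 0.25)
  if (length(post_idx) == 0) stop("event does not fit inside the record")
  gap_total <- t[post_idx[1]] - t_cur
  m <- max(1L, ceiling(gap_total / 0.45))
  fill <- t_cur + seq_len(m) * (gap_total / m)
  new_t <- c(t[keep_pre], gen_t, fill[-m], t[post_idx])
  new_series <- build_rr_series(beat_series(c(
    t[keep_pre][1] - series$rr[keep_pre[1]] / 1000, new_t
  )))

  # --- analytic ground truth from the continuous profile
  cross <- function(level, lower, upper) {
    stats::uniroot(function(x) prof(x) - level, lower = lower,
                   upper = upper, tol = 1e-8)$root
  }
  mid1 <- at + mean(phases[1, ])
  midL <- at + mean(phases[n_phases, ])
  onset_raw <- cross(600, at - lead, mid1)
  offset_raw <- cross(600, midL, at + phases[n_phases, 2] + tail_)
  is_severe <- FALSE
  if (rr_nadir > 750) {
    c1 <- cross(750, at - lead, mid1)
    dL <- cross(750, midL, at + phases[n_phases, 2] + tail_)
    is_severe <- (dL - c1) >= 10
  }
  # first point where d(profile)/dt > 1 ms/s, on the initial descent
  rise_fit <- list(A = rr_base, B = rr_nadir - rr_base, t0 = at + phases[1, 1],
                   s = s, degenerate = FALSE,
                   max_slope = (rr_nadir - rr_base) / (4 * s))
  onset_adj_true <- sigmoid_slope_crossing(rise_fit, 1)

  truth <- data.frame(
    onset_raw = unname(onset_raw), offset_raw = unname(offset_raw),
    duration = offset_raw - onset_raw, n_phases = as.integer(n_phases),
    min_hr = nadir, onset_adj_true = unname(onset_adj_true),
    B100_5 = (offset_raw - onset_raw) >= 5, B80_10 = is_severe
  )
  attr(new_series, "injected_spans") <- rbind(spans, span)
  list(series = new_series, truth = truth)
}

#' Simulate an SpO2 series coupled to bradycardia events
#'
#' 1 Hz oxygen-saturation series: a per-record baseline in 95-99% with
#' small noise; for events flagged with a desaturation, SpO2 falls by
#' `depth` points starting 2-5 s before the bradycardia onset (apneas and
#' desaturations typically precede the bradycardia) and recovers a few
#' seconds after the event offset.
#'
#' @param duration seconds.
#' @param events data.frame with `onset_raw`, `offset_raw` and logical
#'   `desat`; may have zero rows.
#' @param depth desaturation depth(s), percentage points (recycled).
#' @param baseline baseline SpO2, percent.
#' @param noise_sd measurement noise, percentage points.
#' @return A data.frame with columns `time_s` and `spo2`.
#' @export
simulate_spo2 <- function(duration, events = NULL, depth = 15,
                          baseline = NULL, noise_sd = 0.4) {
  time_s <- seq(0, duration, by = 1)
  if (is.null(baseline)) baseline <- stats::runif(1, 95, 99)
  spo2 <- baseline + stats::rnorm(length(time_s), 0, noise_sd)
  if (!is.null(events) && nrow(events) > 0) {
    depth <- rep_len(depth, nrow(events))
    for (i in seq_len(nrow(events))) {
      if (!isTRUE(events$desat[i])) next
      t0 <- events$onset_raw[i] - stats::runif(1, 2, 5)
      t1 <- events$offset_raw[i] + 2
      drop <- depth[i] /
        (1 + exp(-(time_s - t0 - 2) / 1.2)) /
        (1 + exp((time_s - t1 - 3) / 2))
      spo2 <- spo2 - drop
    }
  }
  data.frame(time_s = time_s, spo2 = pmin(spo2, 100))
}

#' Simulate one annotated record
#'
#' Generates a baseline RR series, injects a Poisson number of bradycardia
#' events (non-overlapping, at least 30 s apart), adds beat-detection
#' artifacts away from the events, and couples an SpO2 series. Deep events
#' (nadir below 80 bpm) are always flagged with apnea + desaturation;
#' shallow events with probability `desat_prob`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed for this record.
#' @param record_id identifier stored with the record.
#' @return A list of class `brady_record`: `rr` ([rr_series()]), `spo2`
#'   (data.frame), `truth` (data.frame of ground-truth events with context
#'   flags), `baseline_hr`, `periodic_breathing`, `record_id`, `seed`.
#' @export
simulate_record <- function(config = cohort_config(), seed = 1L,
                            record_id = "rec001") {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  baseline_hr <- min(180, max(125, stats::rnorm(1, config$baseline_hr_mean,
                                                config$baseline_hr_sd)))
  pb <- stats::runif(1) < config$periodic_breathing_prob
  rr <- simulate_baseline(config$record_duration, baseline_hr,
                          config$rr_noise_sd, periodic_breathing = pb)

  # --- draw and place events
  n_ev <- stats::rpois(1, config$event_rate * config$record_duration / 3600)
  truth <- NULL
  if (n_ev > 0) {
    # leave room for the longest morphology (tri: duration + two gaps +
    # recovery tail), so placement does not bias the realized mix
    ats <- sort(stats::runif(n_ev, 60, config$record_duration - 60 -
                               max(config$duration_range) - 26))
    morph <- sample(1:3, n_ev, replace = TRUE, prob = config$morphology_mix)
    nadir <- stats::runif(n_ev, config$depth_range[1], config$depth_range[2])
    dur <- stats::runif(n_ev, config$duration_range[1],
                        config$duration_range[2])
    last_end <- -Inf
    for (i in seq_len(n_ev)) {
      if (ats[i] < last_end + 30) next  # drop colliding placements
      res <- tryCatch(
        inject_event(rr, ats[i], nadir[i], dur[i], morph[i]),
        error = function(e) NULL
      )
      if (is.null(res)) next
      rr <- res$series
      truth <- rbind(truth, res$truth)
      last_end <- res$truth$offset_raw + 50
    }
  }
  if (is.null(truth)) {
    truth <- data.frame(onset_raw = numeric(0), offset_raw = numeric(0),
                        duration = numeric(0), n_phases = integer(0),
                        min_hr = numeric(0), onset_adj_true = numeric(0),
                        B100_5 = logical(0), B80_10 = logical(0))
  }

  # --- context flags and desaturation coupling
  n <- nrow(truth)
  truth$desat <- truth$min_hr < 80 | stats::runif(n) < config$desat_prob
  truth$apnea_flag <- truth$desat
  truth$spo2_drop <- ifelse(truth$desat, stats::runif(n, 12, 25), 0)
  truth$periodic_breathing_flag <- rep(pb, n)
  truth$low_basal_hr_flag <- rep(baseline_hr < 120, n)

  # --- artifacts, away from events
  n_art <- stats::rpois(1, config$artifact_rate *
                          config$record_duration / 3600)
  if (n_art > 0) {
    spans <- attr(rr, "injected_spans")
    for (j in seq_len(n_art)) {
      ta <- stats::runif(1, 30, config$record_duration - 30)
      if (!is.null(spans) &&
          any(ta > spans[, 1] - 15 & ta < spans[, 2] + 15)) next
      k <- findInterval(ta, rr$beat_time)
      if (k < 2 || k > nrow(rr) - 2) next
      beats <- unclass(beats_from_rr(rr))
      if (stats::runif(1) < 0.5) {
        beats <- beats[-(k + 1L)]          # missed beat: one RR doubles
      } else {
        mid <- (beats[k] + beats[k + 1L]) / 2
        beats <- sort(c(beats, mid))       # spurious beat: one RR splits
      }
      sp <- attr(rr, "injected_spans")
      rr <- build_rr_series(beat_series(beats))
      attr(rr, "injected_spans") <- sp
    }
  }

  spo2 <- simulate_spo2(config$record_duration, truth,
                        depth = if (n) truth$spo2_drop else 15)
  structure(
    list(rr = rr, spo2 = spo2, truth = truth, baseline_hr = baseline_hr,
         periodic_breathing = pb, record_id = record_id, seed = seed),
    class = "brady_record"
  )
}

#' Simulate a full annotated cohort
#'
#' Generates `config$n_records` records with per-record seeds derived from
#' the master seed; fully reproducible for a fixed configuration.
#'
#' @param config a [cohort_config()].
#' @return A list of class `brady_cohort`: `records` (list of
#'   [simulate_record()] outputs) and `config`.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_config(n_records = 2, seed = 7))
#' sum(vapply(coh$records, function(r) nrow(r$truth), integer(1)))
#' }
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  seeds <- sample.int(2147483646L, config$n_records)
  records <- lapply(seq_len(config$n_records), function(i) {
    simulate_record(config, seed = seeds[i],
                    record_id = sprintf("rec%03d", i))
  })
  structure(list(records = records, config = config),
            class = "brady_cohort")
}

#' @export
print.brady_record <- function(x, ...) {
  cat(sprintf(
    "<brady_record %s> %.0f s, baseline %.0f bpm, %d event(s)%s\n",
    x$record_id, max(x$rr$beat_time), x$baseline_hr, nrow(x$truth),
    if (x$periodic_breathing) ", periodic breathing" else ""
  ))
  invisible(x)
}

#' @export
print.brady_cohort <- function(x, ...) {
  n_ev <- sum(vapply(x$records, function(r) nrow(r$truth), integer(1)))
  cat(sprintf("<brady_cohort> %d records x %.0f s, %d ground-truth event(s)\n",
              length(x$records), x$config$record_duration, n_ev))
  invisible(x)
}
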