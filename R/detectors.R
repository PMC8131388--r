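#' Detector parameter sets
#'
#' Constructors for the three online detectors' parameters. Defaults are
#' the published operating points for the two NICU alarm tiers:
#' \describe{
#'   \item{yellow}{targets events below 100 bpm for at least 5 s:
#'     U0 = 600 ms, U1 = 640 ms.}
#'   \item{red}{targets events below 80 bpm for at least 10 s:
#'     U0 = 750 ms, U1 = 800 ms.}
#' }
#' Both tiers share the run rule (`RR > U0` for a cumulative duration of
#' more than 4 s, with at least 2 intervals above the confirmation
#' threshold U1) and the Page-Hinkley triple (290 s baseline window,
#' lambda = 717, nu = 415); only one Page-Hinkley parameter set is
#' published.
#'
#' @param U0 primary RR threshold, ms.
#' @param U1 confirmation RR threshold, ms (U1 >= U0).
#' @param min_duration minimum cumulative run duration, seconds (strict
#'   "more than").
#' @param min_occurrences minimum number of intervals above U1 within the run.
#' @param factor multiplier on the trailing-mean RR giving the adaptive
#'   primary threshold U0'(k).
#' @param mean_window trailing-mean window, seconds.
#' @param warmup seconds of history required before the adaptive detector is
#'   armed (cold-start guard; defaults to `mean_window`).
#' @param baseline_window trailing window for the Page-Hinkley baseline mean
#'   RR0bar, seconds.
#' @param lambda Page-Hinkley alarm threshold on the cumulative statistic, ms.
#' @param nu assumed RR jump magnitude (cardiac cycle lengthening), ms.
#' @return A parameter list of class `fixed_params`, `adaptive_params` or
#'   `ph_params` respectively.
#' @name detector-params
NULL

#' @rdname detector-params
#' @export
fixed_params <- function(U0 = 750, U1 = 800, min_duration = 4,
                         min_occurrences = 2) {
  stopifnot(U0 > 0, U1 >= U0, min_duration > 0, min_occurrences >= 1)
  structure(list(U0 = U0, U1 = U1, min_duration = min_duration,
                 min_occurrences = min_occurrences),
            class = "fixed_params")
}

#' @rdname detector-params
#' @export
adaptive_params <- function(factor = 1.33, mean_window = 20, U1 = 800,
                            min_duration = 4, min_occurrences = 2,
                            warmup = mean_window) {
  stopifnot(factor > 1, mean_window > 0, U1 > 0, min_duration > 0,
            min_occurrences >= 1, warmup >= 0)
  structure(list(factor = factor, mean_window = mean_window, U1 = U1,
                 min_duration = min_duration,
                 min_occurrences = min_occurrences, warmup = warmup),
            class = "adaptive_params")
}

#' @rdname detector-params
#' @export
ph_params <- function(baseline_window = 290, lambda = 717, nu = 415) {
  stopifnot(baseline_window > 0, lambda > 0, nu > 0)
  structure(list(baseline_window = baseline_window, lambda = lambda, nu = nu),
            class = "ph_params")
}

#' Full detector configuration for one alarm tier
#'
#' Bundles the three detectors' parameters at their published values for a
#' given alarm color.
#'
#' @param color `"red"` (80 bpm tier) or `"yellow"` (100 bpm tier).
#' @return A list of class `detector_config` with elements `fixed`,
#'   `adaptive`, `ph` and `color`.
#' @examples
#' detector_config("yellow")$fixed$U0  # 600
#' @export
detector_config <- function(color = c("red", "yellow")) {
  color <- match.arg(color)
  if (color == "red") {
    cfg <- list(fixed = fixed_params(U0 = 750, U1 = 800),
                adaptive = adaptive_params(U1 = 800),
                ph = ph_params())
  } else {
    cfg <- list(fixed = fixed_params(U0 = 600, U1 = 640),
                adaptive = adaptive_params(U1 = 640),
                ph = ph_params())
  }
  cfg$color <- color
  structure(cfg, class = "detector_config")
}

#' Alarm trace
#'
#' Per-beat binary alarm level plus the discrete detection instants (the
#' beat times at which the level rises 0 -> 1). Every detector, and the
#' fusion rule, returns one.
#'
#' @param beat_time numeric, seconds, one entry per beat.
#' @param level integer 0/1 alarm level per beat.
#' @return An object of class `alarm_trace`: data.frame with columns
#'   `beat_time`, `level`, and attribute `detections` (numeric seconds).
#' @export
alarm_trace <- function(beat_time, level) {
  level <- as.integer(level)
  stopifnot(length(beat_time) == length(level), all(level %in% c(0L, 1L)))
  rising <- which(level == 1L & c(0L, level[-length(level)]) == 0L)
  structure(
    data.frame(beat_time = as.numeric(beat_time), level = level),
    detections = as.numeric(beat_time[rising]),
    class = c("alarm_trace", "data.frame")
  )
}

#' Detection instants of an alarm trace
#'
#' @param trace an [alarm_trace()].
#' @return Numeric vector of detection times (s), the rising edges of the
#'   alarm level.
#' @export
detections <- function(trace) {
  stopifnot(inherits(trace, "alarm_trace"))
  attr(trace, "detections")
}

#' @export
print.alarm_trace <- function(x, ...) {
  d <- attr(x, "detections")
  cat(sprintf("<alarm_trace> %d beats, %d detection(s)%s\n", nrow(x),
              length(d),
              if (length(d)) paste0(" at ", paste(sprintf("%.2f", d),
                                                  collapse = ", "), " s")
              else ""))
  invisible(x)
}

# Shared run logic of the two threshold detectors: level(k) = 1 iff the
# current uninterrupted run of intervals with RR > u0 has cumulative
# duration (sum of its RR, in s) strictly greater than min_duration AND at
# least min_occurrences of its intervals exceed u1. The run resets as soon
# as RR <= u0. `armed` disarms individual beats (cold start): a disarmed
# beat neither extends the run nor raises the level.
threshold_run_levels <- function(rr, u0, u1, min_duration, min_occurrences,
                                 armed = NULL) {
  n <- length(rr)
  if (is.null(armed)) armed <- rep(TRUE, n)
  level <- integer(n)
  run_dur <- 0
  run_cnt <- 0L
  for (k in seq_len(n)) {
    if (armed[k] && rr[k] > u0[k]) {
      run_dur <- run_dur + rr[k] / 1000
      run_cnt <- run_cnt + (rr[k] > u1)
      if (run_dur > min_duration && run_cnt >= min_occurrences) level[k] <- 1L
    } else {
      run_dur <- 0
      run_cnt <- 0L
    }
  }
  level
}

#' Fixed-threshold bradycardia detector
#'
#' Online rule emulating the NICU monitor alarm: an alarm is raised while
#' the current run of consecutive intervals with RR > U0 exceeds a
#' cumulative 4 s and at least two of its intervals exceed U1. The alarm
#' level falls back to 0 at the first interval at or below U0
#' (release-on-recovery).
#'
#' @param series an [rr_series()].
#' @param params a [fixed_params()] set.
#' @return An [alarm_trace()] on the series' beat grid.
#' @examples
#' rr <- rr_series(seq(0.81, by = 0.81, length.out = 10), rep(810, 10))
#' detections(detect_fixed(rr, fixed_params()))  # fires at the 5th beat
#' @export
detect_fixed <- function(series, params = fixed_params()) {
  stopifnot(inherits(series, "rr_series"), inherits(params, "fixed_params"))
  level <- threshold_run_levels(
    series$rr, rep(params$U0, nrow(series)), params$U1,
    params$min_duration, params$min_occurrences
  )
  alarm_trace(series$beat_time, level)
}

#' Relative adaptive-threshold bradycardia detector
#'
#' Same run rule as [detect_fixed()], but the primary threshold tracks the
#' patient's basal rhythm: U0'(k) = factor * mean RR over the intervals of
#' the trailing `mean_window` seconds (current interval excluded). The
#' detector is disarmed until `warmup` seconds of history exist and
#' whenever the trailing mean is undefined.
#'
#' @param series an [rr_series()].
#' @param params an [adaptive_params()] set.
#' @return An [alarm_trace()].
#' @export
detect_adaptive <- function(series, params = adaptive_params()) {
  stopifnot(inherits(series, "rr_series"), inherits(params, "adaptive_params"))
  tmean <- trailing_mean_rr(series, series$beat_time, params$mean_window)
  u0 <- params$factor * tmean
  armed <- !is.na(u0) &
    series$beat_time >= series$beat_time[1] + params$warmup
  u0[is.na(u0)] <- Inf
  level <- threshold_run_levels(
    series$rr, u0, params$U1,
    params$min_duration, params$min_occurrences, armed = armed
  )
  alarm_trace(series$beat_time, level)
}

#' Page-Hinkley abrupt-change bradycardia detector
#'
#' Sequential (CUSUM-type) detection of an upward mean shift of magnitude
#' nu in the RR series. Per beat k the statistic
#' Lambda <- Lambda + RR(k) - RR0bar(k) - nu/2 is accumulated, where
#' RR0bar(k) is the trailing mean RR over the last `baseline_window`
#' seconds (current interval excluded); the running minimum m of Lambda is
#' kept, and an alarm is raised when Lambda - m >= lambda. After an alarm
#' the statistic is reset (Lambda = m = 0) and the alarm level stays 1
#' until the first beat with RR back below RR0bar(k) + nu/2, at which
#' point the detector re-arms and resumes accumulation.
#'
#' While the baseline mean is undefined (start of record) the increment
#' reduces to -nu/2, so the statistic stays at its floor.
#'
#' @param series an [rr_series()].
#' @param params a [ph_params()] set.
#' @return An [alarm_trace()] carrying the per-beat decision statistic
#'   Lambda - m as attribute `"ph_stat"` (NA while the alarm is latched).
#' @export
detect_page_hinkley <- function(series, params = ph_params()) {
  stopifnot(inherits(series, "rr_series"), inherits(params, "ph_params"))
  rr <- series$rr
  n <- length(rr)
  bmean <- trailing_mean_rr(series, series$beat_time, params$baseline_window)
  bmean[is.na(bmean)] <- rr[is.na(bmean)]
  half_nu <- params$nu / 2
  level <- integer(n)
  stat <- rep(NA_real_, n)
  Lambda <- 0
  m <- 0
  alarmed <- FALSE
  for (k in seq_len(n)) {
    if (alarmed) {
      if (rr[k] < bmean[k] + half_nu) {
        alarmed <- FALSE
        Lambda <- 0
        m <- 0
        # fall through: this beat re-enters normal accumulation
      } else {
        level[k] <- 1L
        next
      }
    }
    Lambda <- Lambda + rr[k] - bmean[k] - half_nu
    if (Lambda < m) m <- Lambda
    stat[k] <- Lambda - m
    if (Lambda - m >= params$lambda) {
      level[k] <- 1L
      alarmed <- TRUE
      Lambda <- 0
      m <- 0
    }
  }
  out <- alarm_trace(series$beat_time, level)
  attr(out, "ph_stat") <- stat
  out
}

#' Run one or all detectors on an RR series
#'
#' Convenience wrapper dispatching on method name; `"fusion"` runs all
#' three and fuses them with [fuse_majority()].
#'
#' @param series an [rr_series()].
#' @param method one of `"fixed"`, `"adaptive"`, `"ph"`, `"fusion"`.
#' @param config a [detector_config()]; defaults to the red (80 bpm) tier.
#' @return An [alarm_trace()].
#' @export
detect <- function(series, method = c("fusion", "fixed", "adaptive", "ph"),
                   config = detector_config("red")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "detector_config"))
  switch(method,
    fixed = detect_fixed(series, config$fixed),
    adaptive = detect_adaptive(series, config$adaptive),
    ph = detect_page_hinkley(series, config$ph),
    fusion = fuse_majority(list(
      detect_fixed(series, config$fixed),
      detect_adaptive(series, config$adaptive),
      detect_page_hinkley(series, config$ph)
    ))
  )
}
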