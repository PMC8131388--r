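#' Beat series: timestamps of detected heartbeats
#'
#' A `beat_series` holds the time instants (seconds from record start) of
#' successive detected heartbeats (QRS complexes). Times must be strictly
#' increasing and finite. ECG-level QRS detection is out of scope: beat
#' times are an input to this package.
#'
#' @param times numeric vector of beat times in seconds, strictly increasing.
#' @return An object of class `beat_series` (a numeric vector).
#' @examples
#' beat_series(c(0, 0.4, 0.8, 1.2))
#' @export
beat_series <- function(times) {
  times <- as.numeric(times)
  if (any(!is.finite(times))) {
    stop("beat times must all be finite")
  }
  if (length(times) >= 2 && any(diff(times) <= 0)) {
    stop("beat times must be strictly increasing")
  }
  structure(times, class = "beat_series")
}

#' RR-interval series
#'
#' An `rr_series` pairs each beat-to-beat interval RR(k) = t(k+1) - t(k)
#' (milliseconds) with the time of the beat at which it becomes known.
#' The interval between beats k and k+1 is stamped at t(k+1): a causal,
#' real-time detector can only act on an interval once its closing beat
#' has been observed.
#'
#' @param beat_time numeric, seconds; time of the beat closing each interval,
#'   strictly increasing.
#' @param rr numeric, milliseconds; the interval lengths, all positive.
#' @return An object of class `rr_series`: a data.frame with columns
#'   `beat_time` (s) and `rr` (ms).
#' @seealso [build_rr_series()] to derive one from a [beat_series()].
#' @export
rr_series <- function(beat_time, rr) {
  beat_time <- as.numeric(beat_time)
  rr <- as.numeric(rr)
  if (length(beat_time) != length(rr)) {
    stop("beat_time and rr must have the same length")
  }
  if (any(!is.finite(beat_time)) || any(!is.finite(rr))) {
    stop("rr_series values must be finite")
  }
  if (any(rr <= 0)) {
    stop("all RR intervals must be positive")
  }
  if (length(beat_time) >= 2 && any(diff(beat_time) <= 0)) {
    stop("beat_time must be strictly increasing")
  }
  structure(
    data.frame(beat_time = beat_time, rr = rr),
    class = c("rr_series", "data.frame")
  )
}

#' Build an RR series from beat times
#'
#' Computes RR(k) = t(k+1) - t(k), in milliseconds, stamped at the later
#' beat t(k+1).
#'
#' @param beats a [beat_series()] (or plain numeric vector of beat times)
#'   with at least two beats.
#' @return An [rr_series()] with one fewer entry than there are beats.
#' @examples
#' build_rr_series(beat_series(c(0, 0.4, 0.8)))  # 400, 400 ms at 0.4, 0.8 s
#' @export
build_rr_series <- function(beats) {
  if (!inherits(beats, "beat_series")) beats <- beat_series(beats)
  if (length(beats) < 2) {
    stop("at least two beats are required to form an RR interval")
  }
  t <- unclass(beats)
  rr_series(beat_time = t[-1], rr = diff(t) * 1000)
}

#' Recover beat times from an RR series
#'
#' Inverse of [build_rr_series()]: cumulative reconstruction of the beat
#' time axis, anchored so that the first interval closes at the stored
#' `beat_time[1]`.
#'
#' @param series an [rr_series()].
#' @return A [beat_series()] with `length(series$rr) + 1` beats.
#' @export
beats_from_rr <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  t1 <- series$beat_time[1] - series$rr[1] / 1000
  beat_series(t1 + c(0, cumsum(series$rr) / 1000))
}

#' Heart-rate / RR-interval unit conversions
#'
#' HR (bpm) and RR (ms) are reciprocal: rr = 60000 / hr. The NICU alarm
#' thresholds map as 100 bpm <-> 600 ms (yellow) and 80 bpm <-> 750 ms (red).
#'
#' @param hr heart rate in beats per minute, positive.
#' @param rr RR interval in milliseconds, positive.
#' @return The converted value(s).
#' @examples
#' bpm_to_rr(100)  # 600 ms
#' rr_to_bpm(750)  # 80 bpm
#' @export
bpm_to_rr <- function(hr) {
  if (any(!is.finite(hr)) || any(hr <= 0)) stop("heart rate must be positive")
  60000 / hr
}

#' @rdname bpm_to_rr
#' @export
rr_to_bpm <- function(rr) {
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("RR interval must be positive")
  60000 / rr
}

#' Trailing mean RR over a time window
#'
#' Arithmetic mean of the RR values stamped in the half-open window
#' `[at_time - window, at_time)`, i.e. over intervals strictly preceding
#' the current beat. This is the baseline statistic of the adaptive and
#' Page-Hinkley detectors ("all RR values preceding beat k during the
#' last w seconds").
#'
#' @param series an [rr_series()].
#' @param at_time query time(s) in seconds (vectorised).
#' @param window window length in seconds, positive.
#' @return Mean RR in ms per query; `NA` when no interval falls in the window.
#' @export
trailing_mean_rr <- function(series, at_time, window) {
  stopifnot(inherits(series, "rr_series"))
  if (!is.finite(window) || window <= 0) stop("window must be positive")
  t <- series$beat_time
  cs <- c(0, cumsum(series$rr))
  # indices i with t[i] >= at - window and t[i] < at
  hi <- findInterval(at_time, t, left.open = TRUE)        # count of t[i] <  at
  lo <- findInterval(at_time - window, t, left.open = TRUE) # count of t[i] < at - window
  n <- hi - lo
  out <- ifelse(n > 0, (cs[hi + 1] - cs[lo + 1]) / pmax(n, 1), NA_real_)
  out
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> %d intervals, %.1f-%.1f s, mean RR %.1f ms (%.1f bpm)\n",
    nrow(x), min(x$beat_time), max(x$beat_time),
    mean(x$rr), 60000 / mean(x$rr)
  ))
  invisible(x)
}
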