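#' Bradycardia definitions
#'
#' The two threshold-based definitions used for event annotation:
#' \describe{
#'   \item{B100_5}{heart rate below 100 bpm for at least 5 s (yellow tier).}
#'   \item{B80_10}{heart rate below 80 bpm for at least 10 s (red tier,
#'     "severe" bradycardia).}
#' }
#' Clinically-significant bradycardia (Bclin) is not threshold-based; it is
#' decided per event by [classify_clinical()]. Events satisfying B80_10 or
#' Bclin are by construction subsets of the B100_5 events.
#'
#' @param label `"B100_5"` or `"B80_10"`, or a custom label when
#'   `hr_threshold`/`min_duration` are supplied explicitly.
#' @param hr_threshold bpm; events are intervals with HR strictly below this.
#' @param min_duration seconds; minimum (merged) event duration.
#' @return A list of class `brady_definition`.
#' @export
brady_definition <- function(label = c("B100_5", "B80_10"),
                             hr_threshold = NULL, min_duration = NULL) {
  if (is.null(hr_threshold)) {
    label <- match.arg(label)
    hr_threshold <- if (label == "B100_5") 100 else 80
    min_duration <- if (label == "B100_5") 5 else 10
  }
  stopifnot(hr_threshold > 0, min_duration > 0)
  structure(list(label = label, hr_threshold = hr_threshold,
                 min_duration = min_duration),
            class = "brady_definition")
}

#' Clinical context of an event
#'
#' Synchronized observations used by the clinical-significance rule:
#' whether an apnea accompanied the event, the depth of the associated
#' SpO2 desaturation (percentage points), and whether the event occurred
#' during low basal heart rate or periodic-breathing HR oscillations
#' (benign patterns that must not be flagged).
#'
#' @param apnea_flag logical.
#' @param spo2_drop non-negative, percentage points of SpO2 decrease.
#' @param low_basal_hr_flag,periodic_breathing_flag logical.
#' @return A list of class `clinical_context`.
#' @export
clinical_context <- function(apnea_flag = FALSE, spo2_drop = 0,
                             low_basal_hr_flag = FALSE,
                             periodic_breathing_flag = FALSE) {
  stopifnot(spo2_drop >= 0)
  structure(list(apnea_flag = isTRUE(apnea_flag),
                 spo2_drop = spo2_drop,
                 low_basal_hr_flag = isTRUE(low_basal_hr_flag),
                 periodic_breathing_flag = isTRUE(periodic_breathing_flag)),
            class = "clinical_context")
}

# Maximal runs of consecutive TRUE values -> two-column matrix (first, last)
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(first = starts[r$values], last = ends[r$values])
}

# Duration convention: a run of sub-threshold intervals spans from the START
# of its first interval (beat_time - rr/1000) to the beat closing its last
# interval, i.e. elapsed time between first and last sub-threshold beat plus
# the first interval.
run_span <- function(series, first, last) {
  c(start = series$beat_time[first] - series$rr[first] / 1000,
    end = series$beat_time[last])
}

#' Extract bradycardia events from an RR series
#'
#' Finds maximal runs of beats with instantaneous HR (= 60000/RR) strictly
#' below the definition's threshold, merges runs separated by a short
#' recovery into single multiphasic events, and keeps events whose merged
#' duration reaches the definition's minimum.
#'
#' Merging follows the multiphasic-event rule: two HR reductions belong to
#' one event when the recovery between them lasts less than `merge_gap`
#' seconds (default 10 s). Recovery time is measured at the 100 bpm level
#' for every definition: the gap between two phases is the longest run of
#' beats at or above 100 bpm between them. (For the 100 bpm definition this
#' is simply the whole gap; for the 80 bpm definition, a dip that never
#' recovers above 100 bpm remains one event however long the gap.)
#' `merge_gap = 0` disables merging.
#'
#' @param series an [rr_series()].
#' @param definition a [brady_definition()].
#' @param merge_gap seconds; recoveries shorter than this are bridged.
#' @return A data.frame of class `brady_events` with columns `onset_raw`,
#'   `offset_raw` (s), `duration` (s), `n_phases`, `min_hr` (bpm).
#' @examples
#' # 12 s below 80 bpm on a 150 bpm baseline
#' beats <- cumsum(c(rep(0.4, 50), rep(0.9, 14), rep(0.4, 50)))
#' ev <- find_events(build_rr_series(beats), brady_definition("B80_10"))
#' ev$duration
#' @export
find_events <- function(series, definition = brady_definition("B100_5"),
                        merge_gap = 10) {
  stopifnot(inherits(series, "rr_series"),
            inherits(definition, "brady_definition"), merge_gap >= 0)
  rr_thr <- 60000 / definition$hr_threshold
  sub <- series$rr > rr_thr
  empty <- structure(
    data.frame(onset_raw = numeric(0), offset_raw = numeric(0),
               duration = numeric(0), n_phases = integer(0),
               min_hr = numeric(0)),
    class = c("brady_events", "data.frame"), label = definition$label
  )
  if (!any(sub)) return(empty)
  ph <- runs_of(sub)

  # longest >= 100 bpm recovery run strictly between interval indices a..b
  recovery_gap <- function(a, b) {
    if (b < a) return(0)
    idx <- a:b
    rec <- series$rr[idx] <= 600
    if (!any(rec)) return(0)
    rr_ <- runs_of(rec)
    max(apply(rr_, 1, function(r) {
      sp <- run_span(series, idx[r[1]], idx[r[2]])
      sp["end"] - sp["start"]
    }))
  }

  # merge consecutive phases with short recovery between them
  grp <- integer(nrow(ph))
  grp[1] <- 1L
  if (nrow(ph) > 1) {
    for (i in 2:nrow(ph)) {
      gap <- recovery_gap(ph[i - 1, "last"] + 1L, ph[i, "first"] - 1L)
      grp[i] <- if (merge_gap > 0 && gap < merge_gap) grp[i - 1] else
        grp[i - 1] + 1L
    }
  }

  ev <- do.call(rbind, lapply(split(seq_len(nrow(ph)), grp), function(ii) {
    sp_first <- run_span(series, ph[ii[1], "first"], ph[ii[1], "last"])
    sp_last <- run_span(series, ph[ii[length(ii)], "first"],
                        ph[ii[length(ii)], "last"])
    span_idx <- ph[ii[1], "first"]:ph[ii[length(ii)], "last"]
    data.frame(
      onset_raw = unname(sp_first["start"]),
      offset_raw = unname(sp_last["end"]),
      duration = unname(sp_last["end"] - sp_first["start"]),
      n_phases = length(ii),
      min_hr = 60000 / max(series$rr[span_idx])
    )
  }))
  ev <- ev[ev$duration >= definition$min_duration, , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) == 0) return(empty)
  structure(ev, class = c("brady_events", "data.frame"),
            label = definition$label)
}

#' Annotate a record under both threshold definitions
#'
#' Runs [find_events()] under the 100 bpm / 5 s definition and labels each
#' resulting event with whether it also contains a severe (80 bpm / 10 s)
#' event, preserving the subset property: every B80_10 event is a B100_5
#' event.
#'
#' @param series an [rr_series()].
#' @param merge_gap seconds, passed to [find_events()].
#' @return A `brady_events` data.frame with additional logical columns
#'   `B100_5` (all TRUE) and `B80_10`.
#' @export
annotate_events <- function(series, merge_gap = 10) {
  ev <- find_events(series, brady_definition("B100_5"), merge_gap)
  sev <- find_events(series, brady_definition("B80_10"), merge_gap)
  ev$B100_5 <- rep(TRUE, nrow(ev))
  ev$B80_10 <- vapply(seq_len(nrow(ev)), function(i) {
    any(sev$onset_raw < ev$offset_raw[i] & sev$offset_raw > ev$onset_raw[i])
  }, logical(1))
  ev
}

#' Clinical significance of a bradycardia event
#'
#' An event is clinically significant when it is severe (B80_10), or when
#' it is a B100_5 event accompanied by apnea and an SpO2 decrease of at
#' least 10 percentage points. Isolated B100_5 events without
#' desaturation, and B100_5 events explained by low basal heart rate or by
#' periodic-breathing HR oscillations, are not clinically significant.
#'
#' @param event one event: a list or single data.frame row carrying logical
#'   elements `B100_5` and `B80_10` (as produced by [annotate_events()]).
#' @param ctx a [clinical_context()].
#' @return Logical scalar.
#' @export
classify_clinical <- function(event, ctx = clinical_context()) {
  stopifnot(inherits(ctx, "clinical_context"))
  if (!isTRUE(as.logical(event$B100_5))) {
    stop("clinical classification applies only to B100_5 events")
  }
  if (isTRUE(as.logical(event$B80_10))) return(TRUE)
  if (ctx$low_basal_hr_flag || ctx$periodic_breathing_flag) return(FALSE)
  ctx$apnea_flag && ctx$spo2_drop >= 10
}
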