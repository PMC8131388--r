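#' Majority-vote fusion of alarm traces
#'
#' Decentralized fusion of n local detectors: at each beat the fused
#' decision is 1 iff the sum of local binary levels d_i exceeds n/2
#' (strict majority; for the standard n = 3, at least two detectors
#' active). Fused detections are the rising edges of the fused level, so
#' with n = 3 a fused detection occurs at the instant the second detector's
#' level rises.
#'
#' Votes are taken on the per-beat level signals, not on point detections:
#' the majority rule is instantaneous and needs no simultaneity window.
#' All traces must share the same beat grid (detectors run on the same
#' RR series do by construction); traces on different grids are rejected
#' rather than resampled.
#'
#' @param traces list of [alarm_trace()] objects on a common beat grid
#'   (normally 3: fixed, adaptive, Page-Hinkley).
#' @return The fused [alarm_trace()].
#' @examples
#' t <- c(1, 2, 3)
#' tr <- function(lv) alarm_trace(t, lv)
#' detections(fuse_majority(list(tr(c(0,1,1)), tr(c(0,0,1)), tr(c(0,0,0)))))
#' @export
fuse_majority <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 2)
  lapply(traces, function(x) stopifnot(inherits(x, "alarm_trace")))
  grid <- traces[[1]]$beat_time
  for (x in traces[-1]) {
    if (length(x$beat_time) != length(grid) ||
        any(abs(x$beat_time - grid) > 1e-9)) {
      stop("alarm traces are not on a common beat grid")
    }
  }
  votes <- Reduce(`+`, lapply(traces, function(x) x$level))
  alarm_trace(grid, as.integer(votes > length(traces) / 2))
}

#' Attribute fused detections to detector subsets
#'
#' For each fused detection instant, records which local detectors' alarm
#' levels were active at that beat, and aggregates the fractions of fused
#' detections produced by the triple and by each pair. This is the
#' "fusion contribution" breakdown (e.g. what share of alarms required
#' all three methods vs the fixed/adaptive pair only).
#'
#' @param fused the fused [alarm_trace()] from [fuse_majority()].
#' @param traces the list of local traces `fused` was derived from.
#' @param names optional character names for the detectors (default
#'   `c("fixed", "adaptive", "ph")` when 3 traces are given).
#' @return A list of class `fusion_breakdown`: `per_detection` (data.frame
#'   with `time` and `subset` label) and `percent` (named numeric,
#'   percentages over all fused detections, summing to 100).
#' @export
attribute_detections <- function(fused, traces, names = NULL) {
  stopifnot(inherits(fused, "alarm_trace"))
  if (is.null(names)) {
    names <- if (length(traces) == 3) c("fixed", "adaptive", "ph")
             else paste0("d", seq_along(traces))
  }
  stopifnot(length(names) == length(traces))
  det <- detections(fused)
  lv <- do.call(cbind, lapply(traces, function(x) x$level))
  idx <- match(det, fused$beat_time)
  subset_lab <- character(length(det))
  for (i in seq_along(det)) {
    active <- which(lv[idx[i], ] == 1L)
    if (length(active) < 2) {
      stop("fused detection with fewer than 2 active local detectors")
    }
    subset_lab[i] <- paste(names[active], collapse = "+")
  }
  all_subsets <- c(paste(names, collapse = "+"),
                   utils::combn(names, 2, paste, collapse = "+"))
  pct <- vapply(all_subsets, function(s) 100 * mean(subset_lab == s),
                numeric(1))
  if (length(det) == 0) pct[] <- NA_real_
  structure(
    list(per_detection = data.frame(time = det, subset = subset_lab,
                                    stringsAsFactors = FALSE),
         percent = pct),
    class = "fusion_breakdown"
  )
}

#' @export
print.fusion_breakdown <- function(x, ...) {
  cat(sprintf("<fusion_breakdown> %d fused detection(s)\n",
              nrow(x$per_detection)))
  for (nm in names(x$percent)) {
    cat(sprintf("  %-22s %5.1f%%\n", nm, x$percent[[nm]]))
  }
  invisible(x)
}
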