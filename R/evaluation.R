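#' Detection-to-annotation matching rules
#'
#' A detection is a true positive when it falls from 5 s before to 30 s
#' after an annotated event onset. `latency_compensation` (default
#' 1.512 s) is added to algorithmic detection instants before matching,
#' accounting for the acquisition and real-time QRS-detection delay of the
#' full chain; set it to 0 for detections that already include their
#' latency (e.g. monitor LED captures).
#'
#' @param pre_window seconds before the onset still accepted (default 5).
#' @param post_window seconds after the onset accepted (default 30).
#' @param latency_compensation seconds added to detection instants
#'   (default 1.512).
#' @return A list of class `match_rules`.
#' @export
match_rules <- function(pre_window = 5, post_window = 30,
                        latency_compensation = 1.512) {
  stopifnot(pre_window >= 0, post_window >= 0)
  structure(list(pre_window = pre_window, post_window = post_window,
                 latency_compensation = latency_compensation),
            class = "match_rules")
}

#' Match detections against annotated event onsets
#'
#' Greedy first-detection-wins matching in time order:
#' \itemize{
#'   \item a detection d (after latency compensation) matches annotation a
#'     when `onset(a) - pre_window <= d <= onset(a) + post_window`;
#'   \item within one annotation's window only the first detection is the
#'     TP; later detections in the same window are ignored (not FP);
#'   \item when one detection falls in the windows of two annotations, it
#'     yields a single TP and the second annotation is ignored (not FN);
#'   \item remaining detections are FP, remaining annotations FN.
#' }
#' The TP delay is the compensated detection instant minus the annotated
#' (adjusted) onset.
#'
#' @param onsets numeric, annotated event onsets (s), sorted increasing.
#'   Use adjusted onsets for delay reporting.
#' @param dets numeric, detection instants (s), sorted increasing.
#' @param rules a [match_rules()].
#' @return A list of class `match_result`: `tp` (data.frame `onset`,
#'   `detection`, `delay`), `fp`, `fn`, `ignored_detections`,
#'   `ignored_annotations`.
#' @examples
#' m <- match_detections(100, 97, match_rules(latency_compensation = 0))
#' m$tp$delay  # -3
#' @export
match_detections <- function(onsets, dets, rules = match_rules()) {
  stopifnot(inherits(rules, "match_rules"))
  if (is.unsorted(onsets, strictly = FALSE) ||
      is.unsorted(dets, strictly = FALSE)) {
    stop("onsets and detections must be sorted in time")
  }
  d <- dets + rules$latency_compensation
  na <- length(onsets)
  nd <- length(d)
  ann_state <- rep("open", na)   # open | matched | ignored
  det_state <- rep("fp", nd)     # fp | tp | ignored
  tp <- data.frame(onset = numeric(0), detection = numeric(0),
                   delay = numeric(0))
  for (i in seq_len(nd)) {
    in_win <- which(d[i] >= onsets - rules$pre_window &
                    d[i] <= onsets + rules$post_window)
    if (length(in_win) == 0) next
    open <- in_win[ann_state[in_win] == "open"]
    if (length(open) > 0) {
      a <- open[1]
      ann_state[a] <- "matched"
      det_state[i] <- "tp"
      tp <- rbind(tp, data.frame(onset = onsets[a], detection = d[i],
                                 delay = d[i] - onsets[a]))
      if (length(open) > 1) ann_state[open[-1]] <- "ignored"
    } else {
      det_state[i] <- "ignored"  # window already served by an earlier TP
    }
  }
  structure(
    list(tp = tp,
         fp = dets[det_state == "fp"],
         fn = onsets[ann_state == "open"],
         ignored_detections = dets[det_state == "ignored"],
         ignored_annotations = onsets[ann_state == "ignored"]),
    class = "match_result"
  )
}

#' Summary metrics of a match result
#'
#' Sensitivity = 100 * TP / (TP + FN); false alarm rate =
#' 100 * FP / (FP + TP); delay mean and sample sd over TP delays. Metrics
#' with a zero denominator are `NA`; the delay sd is `NA` with fewer than
#' two TPs.
#'
#' @param match a [match_detections()] result, or a list of them (pooled).
#' @return A list of class `eval_report`: `n_tp`, `n_fp`, `n_fn`,
#'   `sensitivity`, `false_alarm_rate` (percent), `delay_mean`, `delay_sd`
#'   (s), `delays` (numeric vector).
#' @export
detection_metrics <- function(match) {
  if (inherits(match, "match_result")) match <- list(match)
  n_tp <- sum(vapply(match, function(m) nrow(m$tp), integer(1)))
  n_fp <- sum(vapply(match, function(m) length(m$fp), integer(1)))
  n_fn <- sum(vapply(match, function(m) length(m$fn), integer(1)))
  delays <- unlist(lapply(match, function(m) m$tp$delay))
  structure(
    list(n_tp = n_tp, n_fp = n_fp, n_fn = n_fn,
         sensitivity = if (n_tp + n_fn > 0) 100 * n_tp / (n_tp + n_fn)
                       else NA_real_,
         false_alarm_rate = if (n_tp + n_fp > 0) 100 * n_fp / (n_tp + n_fp)
                            else NA_real_,
         delay_mean = if (n_tp > 0) mean(delays) else NA_real_,
         delay_sd = if (n_tp > 1) stats::sd(delays) else NA_real_,
         delays = delays),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> TP %d  FP %d  FN %d | Se %.1f%%  FAR %.1f%%  delay %.2f (%.2f) s\n",
    x$n_tp, x$n_fp, x$n_fn, x$sensitivity, x$false_alarm_rate,
    x$delay_mean, x$delay_sd
  ))
  invisible(x)
}

#' Paired comparison of detection delays
#'
#' Two-sided Wilcoxon signed-rank test on paired delays (events detected
#' by both detectors); used because detection delays are not normally
#' distributed. Significance is conventionally read at alpha = 0.05.
#'
#' @param delays_a,delays_b equal-length paired delay vectors (s).
#' @return A list: `statistic` (V), `p_value`, `n`, `degenerate` (TRUE
#'   when all pairwise differences are zero, in which case the p-value is
#'   `NA`).
#' @export
compare_delays <- function(delays_a, delays_b) {
  stopifnot(length(delays_a) == length(delays_b))
  diffs <- delays_a - delays_b
  if (length(diffs) < 1 || all(diffs == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                n = length(diffs), degenerate = TRUE))
  }
  wt <- stats::wilcox.test(delays_a, delays_b, paired = TRUE,
                           exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = length(diffs), degenerate = FALSE)
}

#' Benchmark detectors against cohort ground truth
#'
#' Runs each detector over every record of a synthetic cohort, matches its
#' detections against the ground-truth annotations of a given definition,
#' and pools TP/FP/FN across records into one report row per detector,
#' plus a paired Wilcoxon comparison of delays on the events detected by
#' every detector (common TPs).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param detector_specs named list; each element is a list with `fn` (a
#'   function `rr_series -> alarm_trace`) and optional `latency` (seconds
#'   added to its detections before matching; defaults to
#'   `rules$latency_compensation`).
#' @param definition which ground-truth label to score against:
#'   `"B80_10"` or `"B100_5"`.
#' @param rules a [match_rules()].
#' @param use_adjusted_onsets score delays against the true
#'   sigmoid-adjusted onsets (default) rather than the raw
#'   threshold-crossing onsets.
#' @return A list of class `benchmark_result`: `table` (one row per
#'   detector: n_events, n_tp, n_fp, n_fn, sensitivity, false_alarm_rate,
#'   delay_mean, delay_sd), `reports` (named list of `eval_report`),
#'   `paired` (data.frame of pairwise Wilcoxon comparisons on common TPs).
#' @export
benchmark <- function(cohort, detector_specs,
                      definition = c("B80_10", "B100_5"),
                      rules = match_rules(),
                      use_adjusted_onsets = TRUE) {
  stopifnot(inherits(cohort, "brady_cohort"), length(detector_specs) >= 1,
            !is.null(names(detector_specs)))
  definition <- match.arg(definition)
  if (length(cohort$records) == 0) stop("empty cohort")

  onset_col <- if (use_adjusted_onsets) "onset_adj_true" else "onset_raw"
  det_names <- names(detector_specs)
  matches <- stats::setNames(
    lapply(det_names, function(x) vector("list", length(cohort$records))),
    det_names
  )
  # per-record, per-detector matching
  for (r in seq_along(cohort$records)) {
    rec <- cohort$records[[r]]
    truth <- rec$truth[rec$truth[[definition]], , drop = FALSE]
    onsets <- sort(truth[[onset_col]])
    for (nm in det_names) {
      spec <- detector_specs[[nm]]
      lat <- if (is.null(spec$latency)) rules$latency_compensation
             else spec$latency
      r_rules <- match_rules(rules$pre_window, rules$post_window, lat)
      dets <- sort(detections(spec$fn(rec$rr)))
      matches[[nm]][[r]] <- match_detections(onsets, dets, r_rules)
    }
  }
  reports <- lapply(matches, detection_metrics)
  tab <- do.call(rbind, lapply(det_names, function(nm) {
    rep_ <- reports[[nm]]
    data.frame(detector = nm,
               definition = definition,
               n_events = rep_$n_tp + rep_$n_fn,
               n_tp = rep_$n_tp, n_fp = rep_$n_fp, n_fn = rep_$n_fn,
               sensitivity = rep_$sensitivity,
               false_alarm_rate = rep_$false_alarm_rate,
               delay_mean = rep_$delay_mean, delay_sd = rep_$delay_sd)
  }))

  # pairwise Wilcoxon on common TPs (same annotated onset in same record)
  paired <- NULL
  if (length(det_names) >= 2) {
    keys <- function(nm) {
      do.call(rbind, lapply(seq_along(matches[[nm]]), function(r) {
        tp <- matches[[nm]][[r]]$tp
        if (nrow(tp) == 0) return(NULL)
        data.frame(rec = r, onset = tp$onset, delay = tp$delay)
      }))
    }
    key_list <- lapply(stats::setNames(det_names, det_names), keys)
    for (i in seq_len(length(det_names) - 1)) {
      for (j in seq.int(i + 1, length(det_names))) {
        a <- key_list[[det_names[i]]]
        b <- key_list[[det_names[j]]]
        if (is.null(a) || is.null(b)) next
        common <- merge(a, b, by = c("rec", "onset"),
                        suffixes = c("_a", "_b"))
        cmp <- compare_delays(common$delay_a, common$delay_b)
        paired <- rbind(paired, data.frame(
          detector_a = det_names[i], detector_b = det_names[j],
          n_common = cmp$n, statistic = cmp$statistic,
          p_value = cmp$p_value
        ))
      }
    }
  }
  structure(list(table = tab, reports = reports, paired = paired,
                 matches = matches),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$paired)) {
    cat("\nPaired delay comparisons (Wilcoxon signed-rank, common TPs):\n")
    print(x$paired, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
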