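#' Read / write RR-series and beat-time CSV files
#'
#' RR series are stored as two-column CSV `time_s,rr_ms` (header required,
#' '.' decimal separator, UTF-8); beat-time files as one column `time_s`.
#'
#' @param path file path.
#' @param series an [rr_series()].
#' @return `read_rr_csv` returns an [rr_series()]; `read_beats_csv` a
#'   [beat_series()]; the writers return `path` invisibly.
#' @name rr-io
NULL

check_numeric_cols <- function(df, cols, path) {
  if (!all(cols %in% names(df))) {
    stop(sprintf("%s: expected header with columns %s", path,
                 paste(cols, collapse = ", ")))
  }
  for (cc in cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value in column '%s' at data line %d",
                   path, cc, bad[1]))
    }
  }
}

#' @rdname rr-io
#' @export
read_rr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_numeric_cols(df, c("time_s", "rr_ms"), path)
  rr_series(beat_time = as.numeric(df$time_s), rr = as.numeric(df$rr_ms))
}

#' @rdname rr-io
#' @export
write_rr_csv <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  utils::write.csv(data.frame(time_s = series$beat_time, rr_ms = series$rr),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname rr-io
#' @export
read_beats_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_numeric_cols(df, "time_s", path)
  beat_series(as.numeric(df$time_s))
}

#' @rdname rr-io
#' @export
write_beats_csv <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  utils::write.csv(data.frame(time_s = unclass(beats)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write alarm traces and detection lists
#'
#' An alarm trace is written as CSV `time_s,level`; the detection instants
#' alone as a JSON object `{schema, detections_s}`.
#'
#' @param trace an [alarm_trace()].
#' @param path file path.
#' @name alarm-io
NULL

#' @rdname alarm-io
#' @export
write_alarm_csv <- function(trace, path) {
  stopifnot(inherits(trace, "alarm_trace"))
  utils::write.csv(data.frame(time_s = trace$beat_time, level = trace$level),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname alarm-io
#' @export
read_alarm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_numeric_cols(df, c("time_s", "level"), path)
  alarm_trace(as.numeric(df$time_s), as.integer(df$level))
}

#' @rdname alarm-io
#' @export
write_detections_json <- function(trace, path) {
  dets <- if (inherits(trace, "alarm_trace")) detections(trace)
          else as.numeric(trace)
  jsonlite::write_json(
    list(schema = "bradyfusion/detections/v1", detections_s = dets),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname alarm-io
#' @export
read_detections_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$detections_s)) {
    stop(path, ": not a detections JSON (missing 'detections_s')")
  }
  as.numeric(obj$detections_s)
}

#' Read / write event annotation files
#'
#' Events are stored as a JSON list of objects with onset/offset (raw and,
#' when available, adjusted), labels and per-event context flags, or as a
#' flat CSV with one row per event.
#'
#' @param events a `brady_events` / truth data.frame.
#' @param path file path.
#' @name event-io
NULL

#' @rdname event-io
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(
    list(schema = "bradyfusion/events/v1",
         events = as.data.frame(events)),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname event-io
#' @export
read_events_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$events)) stop(path, ": not an events JSON")
  ev <- as.data.frame(obj$events)
  if (nrow(ev) > 0 && !all(c("onset_raw", "offset_raw") %in% names(ev))) {
    stop(path, ": events JSON lacks onset_raw/offset_raw fields")
  }
  ev
}

#' Read / write detector configuration YAML
#'
#' One block per detector (`fixed`, `adaptive`, `ph`) plus the alarm
#' `color`; unspecified fields keep the published defaults of
#' [detector_config()], unknown fields are rejected.
#'
#' @param config a [detector_config()].
#' @param path file path.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "detector_config"))
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  color <- if (is.null(obj$color)) "red" else obj$color
  cfg <- detector_config(color)
  for (block in c("fixed", "adaptive", "ph")) {
    if (is.null(obj[[block]])) next
    known <- names(cfg[[block]])
    unknown <- setdiff(names(obj[[block]]), known)
    if (length(unknown)) {
      stop(path, ": unknown key(s) in '", block, "': ",
           paste(unknown, collapse = ", "))
    }
    cfg[[block]][names(obj[[block]])] <- obj[[block]]
  }
  ctor <- list(fixed = fixed_params, adaptive = adaptive_params,
               ph = ph_params)
  for (block in names(ctor)) {
    cfg[[block]] <- do.call(ctor[[block]], unclass(cfg[[block]]))
  }
  cfg
}

#' Write a synthetic record / cohort to plain-text files
#'
#' Each record produces `<id>_rr.csv`, `<id>_spo2.csv` and
#' `<id>_truth.json`; the cohort writer adds a `manifest.json` with the
#' configuration and master seed.
#'
#' @param record a [simulate_record()] result.
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_record <- function(record, dir = ".") {
  stopifnot(inherits(record, "brady_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- record$record_id
  write_rr_csv(record$rr, file.path(dir, paste0(id, "_rr.csv")))
  utils::write.csv(record$spo2, file.path(dir, paste0(id, "_spo2.csv")),
                   row.names = FALSE, quote = FALSE)
  write_events_json(record$truth, file.path(dir, paste0(id, "_truth.json")))
  invisible(dir)
}

#' @rdname write_record
#' @export
write_cohort <- function(cohort, dir = ".") {
  stopifnot(inherits(cohort, "brady_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$records) write_record(rec, dir)
  jsonlite::write_json(
    list(schema = "bradyfusion/cohort-manifest/v1",
         config = unclass(cohort$config),
         records = vapply(cohort$records, `[[`, "", "record_id")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Write a benchmark table as CSV
#'
#' Columns: detector, definition, n_events, sensitivity_pct, far_pct,
#' delay_mean_s, delay_sd_s, p_wilcoxon (the paired p-value against the
#' first detector, where available).
#'
#' @param bench a [benchmark()] result.
#' @param path file path.
#' @export
write_report_csv <- function(bench, path) {
  stopifnot(inherits(bench, "benchmark_result"))
  tab <- bench$table
  p <- rep(NA_real_, nrow(tab))
  if (!is.null(bench$paired)) {
    for (i in seq_len(nrow(tab))) {
      hit <- which(bench$paired$detector_b == tab$detector[i] &
                     bench$paired$detector_a == tab$detector[1])
      if (length(hit)) p[i] <- bench$paired$p_value[hit[1]]
    }
  }
  out <- data.frame(detector = tab$detector, definition = tab$definition,
                    n_events = tab$n_events,
                    sensitivity_pct = tab$sensitivity,
                    far_pct = tab$false_alarm_rate,
                    delay_mean_s = tab$delay_mean,
                    delay_sd_s = tab$delay_sd,
                    p_wilcoxon = p)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
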