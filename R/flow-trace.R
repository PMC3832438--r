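#' Carotid blood-flow recording
#'
#' Container for one animal's Doppler flow trace: sample times in seconds
#' from the start of recording, flow in ml/min, and named experiment-phase
#' markers (seconds). Recognized markers are `recording_start`, `fecl3_on`,
#' `fecl3_off`, `occlusion_confirmed` and `drug_start`; all are optional but
#' must lie within the recorded span, and `drug_start` may not precede
#' `occlusion_confirmed`.
#'
#' @param time_s strictly increasing sample times, seconds
#' @param flow flow values, ml/min
#' @param animal_id label
#' @param markers named list or vector of marker times, seconds
#' @return an object of class `flow_trace`
#' @export
flow_trace <- function(time_s, flow, animal_id = "", markers = list()) {
  if (length(time_s) == 0L)
    stop_with("thrombolyzer_empty_trace", "trace has no samples")
  if (length(time_s) != length(flow))
    stop_with("thrombolyzer_invalid_input", "time and flow lengths differ")
  if (any(!is.finite(time_s)) || any(!is.finite(flow)))
    stop_with("thrombolyzer_invalid_input", "non-finite values in trace")
  bad <- which(diff(time_s) <= 0)
  if (length(bad))
    stop_with("thrombolyzer_nonmonotone_time",
              sprintf("time is not strictly increasing at row %d", bad[1] + 1L))
  markers <- as.list(markers)
  span <- range(time_s)
  for (m in names(markers)) {
    mt <- markers[[m]]
    if (!is.numeric(mt) || length(mt) != 1L || !is.finite(mt))
      stop_with("thrombolyzer_invalid_input",
                sprintf("marker `%s` must be a single time in seconds", m))
    if (mt < span[1] || mt > span[2])
      stop_with("thrombolyzer_invalid_input",
                sprintf("marker `%s` (%g s) lies outside the recorded span", m, mt))
  }
  if (!is.null(markers$drug_start) && !is.null(markers$occlusion_confirmed) &&
      markers$drug_start < markers$occlusion_confirmed)
    stop_with("thrombolyzer_invalid_input",
              "`drug_start` precedes `occlusion_confirmed`")
  structure(list(animal_id = animal_id, time_s = as.numeric(time_s),
                 flow = as.numeric(flow), markers = markers),
            class = "flow_trace")
}

#' @export
print.flow_trace <- function(x, ...) {
  cat(sprintf("<flow_trace> %s: %d samples, %.1f-%.1f s\n",
              if (nzchar(x$animal_id)) x$animal_id else "(unnamed)",
              length(x$time_s), min(x$time_s), max(x$time_s)))
  if (length(x$markers))
    cat("  markers:", paste(sprintf("%s=%gs", names(x$markers),
                                    unlist(x$markers)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.flow_trace <- function(x, ...) {
  data.frame(time_s = x$time_s, flow = x$flow)
}

#' Read a flow trace from CSV (+ optional sidecar marker JSON)
#'
#' The CSV must have columns `time_s` and `flow`. Markers come from a
#' sidecar JSON file (named marker -> seconds), a named list, or are omitted.
#' Negative flow values are clipped to 0 and the count of clipped samples is
#' reported via a message and stored in attribute `n_clipped`.
#'
#' @param path CSV path
#' @param markers path to a marker JSON file, or a named list of marker
#'   times in seconds, or `NULL`
#' @param animal_id label; defaults to the file stem
#' @return a [flow_trace()]
#' @export
read_flow_trace <- function(path, markers = NULL, animal_id = NULL) {
  if (!file.exists(path))
    stop_with("thrombolyzer_missing_file", sprintf("no such file: %s", path))
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop_with("thrombolyzer_empty_file",
                                               sprintf("cannot parse %s: %s", path,
                                                       conditionMessage(e))))
  if (nrow(df) == 0L)
    stop_with("thrombolyzer_empty_file", sprintf("%s contains no samples", path))
  missing_cols <- setdiff(c("time_s", "flow"), names(df))
  if (length(missing_cols))
    stop_with("thrombolyzer_missing_column",
              sprintf("%s lacks column(s): %s", path,
                      paste(missing_cols, collapse = ", ")))
  if (is.character(markers)) markers <- jsonlite::read_json(markers)
  n_neg <- sum(df$flow < 0)
  if (n_neg > 0) {
    message(sprintf("read_flow_trace: clipped %d negative flow value(s) to 0",
                    n_neg))
    df$flow <- pmax(df$flow, 0)
  }
  tr <- flow_trace(df$time_s, df$flow,
                   animal_id = animal_id %||%
                     sub("\\.[^.]*$", "", basename(path)),
                   markers = markers %||% list())
  attr(tr, "n_clipped") <- n_neg
  tr
}

#' Write a flow trace to CSV (+ sidecar marker JSON)
#'
#' Emits the same dialect [read_flow_trace()] consumes.
#'
#' @param trace a [flow_trace()]
#' @param path output CSV path
#' @param markers_path output JSON path for markers; default replaces the
#'   CSV extension with `.json`; `NA` suppresses the sidecar
#' @return `path`, invisibly
#' @export
write_flow_trace <- function(trace, path, markers_path = NULL) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  if (!isTRUE(is.na(markers_path)) && length(trace$markers)) {
    mp <- markers_path %||% sub("\\.[^.]*$", ".json", path)
    jsonlite::write_json(trace$markers, mp, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
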