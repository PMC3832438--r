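#' Impedance aggregometry trace
#'
#' Whole-blood platelet aggregation recording: impedance (ohms) across the
#' electrode pair versus time. The agonist (20 uM ADP or 5 ug/ml collagen)
#' is added after a short baseline; in disaggregation experiments the test
#' agent is added at `addition_time_s`, after maximal aggregation.
#'
#' @param time_s strictly increasing sample times, seconds
#' @param impedance_ohm impedance values, ohms, finite
#' @param agonist agonist label
#' @param treatment_dose test-agent amount, ug
#' @param addition_time_s time the test agent was added (disaggregation
#'   mode), seconds, or `NULL`
#' @param agonist_time_s time the agonist was added, seconds
#' @return an object of class `agg_trace`
#' @export
agg_trace <- function(time_s, impedance_ohm, agonist = "ADP",
                      treatment_dose = 0, addition_time_s = NULL,
                      agonist_time_s = 30) {
  if (length(time_s) == 0L)
    stop_with("thrombolyzer_empty_trace", "trace has no samples")
  if (any(diff(time_s) <= 0))
    stop_with("thrombolyzer_nonmonotone_time",
              "time is not strictly increasing")
  if (any(!is.finite(impedance_ohm)))
    stop_with("thrombolyzer_invalid_input", "impedance must be finite")
  if (!is.null(addition_time_s) &&
      (addition_time_s < min(time_s) || addition_time_s > max(time_s)))
    stop_with("thrombolyzer_invalid_input",
              "`addition_time_s` lies outside the recorded span")
  structure(list(time_s = as.numeric(time_s),
                 impedance_ohm = as.numeric(impedance_ohm),
                 agonist = agonist, treatment_dose = treatment_dose,
                 addition_time_s = addition_time_s,
                 agonist_time_s = agonist_time_s),
            class = "agg_trace")
}

#' @export
print.agg_trace <- function(x, ...) {
  cat(sprintf("<agg_trace> %s, dose %g ug: %d samples, max %.1f ohm\n",
              x$agonist, x$treatment_dose, length(x$time_s),
              max(x$impedance_ohm)))
  invisible(x)
}

#' Read an aggregometry trace from CSV (+ sidecar JSON metadata)
#'
#' The CSV must have columns `time_s` and `impedance_ohm`; agonist, dose and
#' addition time come from a sidecar JSON or arguments.
#'
#' @param path CSV path
#' @param meta path to a JSON file with fields `agonist`, `treatment_dose`,
#'   `addition_time_s`, `agonist_time_s`, or a named list, or `NULL`
#' @return an [agg_trace()]
#' @export
read_agg_trace <- function(path, meta = NULL) {
  if (!file.exists(path))
    stop_with("thrombolyzer_missing_file", sprintf("no such file: %s", path))
  df <- utils::read.csv(path)
  missing_cols <- setdiff(c("time_s", "impedance_ohm"), names(df))
  if (length(missing_cols))
    stop_with("thrombolyzer_missing_column",
              sprintf("%s lacks column(s): %s", path,
                      paste(missing_cols, collapse = ", ")))
  if (is.character(meta)) meta <- jsonlite::read_json(meta)
  meta <- meta %||% list()
  agg_trace(df$time_s, df$impedance_ohm,
            agonist = meta$agonist %||% "ADP",
            treatment_dose = meta$treatment_dose %||% 0,
            addition_time_s = meta$addition_time_s,
            agonist_time_s = meta$agonist_time_s %||% 30)
}

# pre-agonist baseline impedance: mean of samples in the window before the
# agonist addition (default: everything before `agonist_time_s`)
agg_baseline <- function(trace, baseline_window_s = NULL) {
  t_ag <- baseline_window_s %||% trace$agonist_time_s %||% 30
  idx <- trace$time_s < t_ag
  if (!any(idx)) return(0)
  mean(trace$impedance_ohm[idx])
}

#' Maximal aggregation above baseline
#'
#' The maximal impedance rise above the pre-agonist baseline (mean of
#' samples recorded before agonist addition, by default the first 30 s).
#' A trace that never rises above baseline yields 0.
#'
#' @param trace an [agg_trace()]
#' @param baseline_window_s end of the baseline window, seconds; defaults to
#'   the trace's agonist addition time
#' @param before_s only consider samples before this time (used internally
#'   to restrict to the pre-treatment phase); default all
#' @return maximal aggregation, ohms
#' @export
max_aggregation <- function(trace, baseline_window_s = NULL,
                            before_s = NULL) {
  stopifnot(inherits(trace, "agg_trace"))
  base <- agg_baseline(trace, baseline_window_s)
  imp <- trace$impedance_ohm
  if (!is.null(before_s)) imp <- imp[trace$time_s <= before_s]
  max(0, max(imp) - base)
}

#' Percent inhibition of aggregation
#'
#' `100 * (1 - a / a0)` for treated maximal aggregation `a` and control
#' maximal aggregation `a0`. Values above 100\% cannot occur for `a >= 0`;
#' negative values (aggregation enhancement) are returned with a warning
#' rather than clamped, so the statistic stays invertible.
#'
#' @param a treated maximal aggregation, ohms (>= 0)
#' @param a0 control maximal aggregation, ohms (> 0)
#' @return percent inhibition
#' @examples
#' percent_inhibition(8, 16)   # 50
#' percent_inhibition(2, 22)   # 90.91
#' @export
percent_inhibition <- function(a, a0) {
  if (!is.numeric(a0) || any(a0 <= 0))
    stop_with("thrombolyzer_invalid_input", "`a0` must be positive")
  if (any(a < 0))
    stop_with("thrombolyzer_invalid_input", "`a` must be non-negative")
  if (any(a > a0))
    warning("a > a0: negative inhibition (enhancement) reported", call. = FALSE)
  100 * (1 - a / a0)
}

#' Percent disaggregation at a fixed readout time
#'
#' Restoration of the impedance toward the pre-agonist baseline, read
#' `readout_s` seconds after the test agent was added to a preformed
#' aggregate: `100 * (a_max - a(t_add + readout)) / (a_max - a_baseline)`,
#' where `a_max` is the maximal impedance reached before addition and
#' `a(t)` is linearly interpolated. 100\% means full return to basal
#' levels. Conventional readouts are 14 s for ADP and 300 s for collagen
#' aggregates (see [agg_readout_defaults()]).
#'
#' @param trace an [agg_trace()] with `addition_time_s` set
#' @param readout_s readout delay after addition, seconds
#' @param baseline_window_s see [max_aggregation()]
#' @return percent disaggregation
#' @export
percent_disaggregation <- function(trace, readout_s,
                                   baseline_window_s = NULL) {
  stopifnot(inherits(trace, "agg_trace"))
  if (is.null(trace$addition_time_s))
    stop_with("thrombolyzer_invalid_input",
              "trace has no `addition_time_s`; not a disaggregation recording")
  t_read <- trace$addition_time_s + readout_s
  if (t_read > max(trace$time_s))
    stop_with("thrombolyzer_invalid_input",
              "readout time lies beyond the end of the trace")
  base <- agg_baseline(trace, baseline_window_s)
  a_max <- max(trace$impedance_ohm[trace$time_s <= trace$addition_time_s]) - base
  if (a_max <= 0)
    stop_with("thrombolyzer_invalid_input",
              "no aggregation above baseline before addition; statistic undefined")
  a_t <- stats::approx(trace$time_s, trace$impedance_ohm, xout = t_read)$y - base
  100 * (a_max - a_t) / a_max
}

#' Conventional disaggregation readout times
#'
#' ADP-induced aggregates resolve within seconds and are read 14 s after
#' addition; collagen-induced aggregates respond slowly and are read at
#' 300 s.
#'
#' @return named numeric vector of readout delays, seconds
#' @export
agg_readout_defaults <- function() c(ADP = 14, collagen = 300)

#' Analyze an aggregometry trace
#'
#' Convenience wrapper producing an `agg_result`: maximal aggregation plus
#' either percent inhibition (against a control trace or a stated control
#' maximal aggregation `a0`) or percent disaggregation at the agonist's
#' conventional readout time.
#'
#' @param trace an [agg_trace()]
#' @param mode `"inhibition"` or `"disaggregation"`
#' @param control control [agg_trace()] (inhibition mode), or `NULL`
#' @param a0 control maximal aggregation in ohms, used when `control` is
#'   `NULL`
#' @param readout_s disaggregation readout delay; defaults to the agonist's
#'   entry in [agg_readout_defaults()]
#' @return an object of class `agg_result`
#' @export
analyze_aggregometry <- function(trace,
                                 mode = c("inhibition", "disaggregation"),
                                 control = NULL, a0 = NULL,
                                 readout_s = NULL) {
  mode <- match.arg(mode)
  a <- max_aggregation(trace)
  res <- list(agonist = trace$agonist, treatment_dose = trace$treatment_dose,
              max_aggregation_ohm = a, inhibition_pct = NA_real_,
              disaggregation_pct = NA_real_, readout_time_s = NA_real_)
  if (mode == "inhibition") {
    if (is.null(a0)) {
      if (is.null(control))
        stop_with("thrombolyzer_invalid_input",
                  "inhibition mode needs a control trace or `a0`")
      a0 <- max_aggregation(control)
    }
    res$inhibition_pct <- percent_inhibition(a, a0)
  } else {
    readout_s <- readout_s %||%
      agg_readout_defaults()[[trace$agonist]] %||% 300
    res$disaggregation_pct <- percent_disaggregation(trace, readout_s)
    res$readout_time_s <- readout_s
  }
  structure(res, class = "agg_result")
}

#' @export
print.agg_result <- function(x, ...) {
  cat(sprintf("<agg_result> %s, %g ug: max aggregation %.2f ohm",
              x$agonist, x$treatment_dose, x$max_aggregation_ohm))
  if (!is.na(x$inhibition_pct))
    cat(sprintf(", inhibition %.2f%%", x$inhibition_pct))
  if (!is.na(x$disaggregation_pct))
    cat(sprintf(", disaggregation %.2f%% at %g s", x$disaggregation_pct,
                x$readout_time_s))
  cat("\n")
  invisible(x)
}
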