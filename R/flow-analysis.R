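#' Baseline carotid flow
#'
#' Arithmetic mean of the flow over the pre-injury baseline window, by
#' default the 5 minutes ending at the `fecl3_on` marker (baseline flow is
#' measured for 5 minutes before FeCl3 application).
#'
#' @param trace a [flow_trace()]
#' @param window_s baseline window length, seconds
#' @param end_s window end, seconds; defaults to the `fecl3_on` marker when
#'   present, else `window_s` from the start of the trace
#' @return baseline flow, ml/min
#' @export
compute_baseline <- function(trace, window_s = 300, end_s = NULL) {
  stopifnot(inherits(trace, "flow_trace"))
  end_s <- end_s %||% trace$markers$fecl3_on %||% (min(trace$time_s) + window_s)
  start_s <- end_s - window_s
  if (start_s < min(trace$time_s) || end_s > max(trace$time_s))
    stop_with("thrombolyzer_invalid_input",
              sprintf("baseline window [%g, %g] s extends outside the trace",
                      start_s, end_s))
  idx <- trace$time_s >= start_s & trace$time_s < end_s
  if (!any(idx))
    stop_with("thrombolyzer_invalid_input", "baseline window holds no samples")
  mean(trace$flow[idx])
}

# contiguous runs of a logical vector; returns start index, end index and
# time-duration of each TRUE run (a sample at t_i covers [t_i, t_{i+1}),
# the final sample extends by the median sampling interval)
true_runs <- function(time_s, flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(data.frame(start = integer(), end = integer(),
                                    duration_s = numeric()))
  n <- length(time_s)
  dt_last <- if (n > 1L) stats::median(diff(time_s)) else 0
  s <- starts[keep]; e <- ends[keep]
  dur <- ifelse(e < n, time_s[e + 1L], time_s[n] + dt_last) - time_s[s]
  data.frame(start = s, end = e, duration_s = dur)
}

#' Detect complete occlusion
#'
#' Complete occlusion is the absence of blood flow for 10 minutes: the
#' first contiguous run of samples with flow below `zero_frac` of baseline
#' lasting at least `duration_s`. The 5\% threshold stands in for the
#' instrument noise floor, since a Doppler meter never reads exactly zero.
#'
#' @param trace a [flow_trace()]
#' @param baseline baseline flow, ml/min (see [compute_baseline()])
#' @param zero_frac zero-flow threshold as a fraction of baseline
#' @param duration_s minimum sustained duration, seconds
#' @param from_s ignore samples before this time; defaults to the
#'   `fecl3_on` marker when present
#' @return start time of occlusion in seconds, or `NA` if never occluded
#' @export
detect_complete_occlusion <- function(trace, baseline, zero_frac = 0.05,
                                      duration_s = 600, from_s = NULL) {
  stopifnot(inherits(trace, "flow_trace"))
  from_s <- from_s %||% trace$markers$fecl3_on %||% min(trace$time_s)
  idx <- trace$time_s >= from_s
  tt <- trace$time_s[idx]
  runs <- true_runs(tt, trace$flow[idx] < zero_frac * baseline)
  hit <- runs$duration_s >= duration_s
  if (!any(hit)) return(NA_real_)
  tt[runs$start[which(hit)[1]]]
}

#' Standardize a trace by its minimum flow
#'
#' Per-animal standardization maps the occluded level to zero so that
#' animals with different physiological offsets are comparable. The default
#' subtracts the per-animal minimum flow from every sample (recorded in
#' attribute `offset`); `method = "ratio"` instead divides by the minimum,
#' which is numerically explosive when the occluded flow is near zero and
#' is provided only for comparison.
#'
#' @param trace a [flow_trace()]
#' @param method `"subtract"` (default) or `"ratio"`
#' @return a standardized [flow_trace()]
#' @export
standardize_trace <- function(trace, method = c("subtract", "ratio")) {
  stopifnot(inherits(trace, "flow_trace"))
  method <- match.arg(method)
  m <- min(trace$flow)
  out <- trace
  if (method == "subtract") {
    out$flow <- trace$flow - m
  } else {
    if (m <= 0)
      stop_with("thrombolyzer_invalid_input",
                "ratio standardization requires a positive minimum flow")
    out$flow <- trace$flow / m
  }
  attr(out, "offset") <- m
  attr(out, "standardize_method") <- method
  out
}

#' Per-minute mean flow
#'
#' Average flow for each whole minute. Bin `k` covers
#' `[origin + 60k, origin + 60(k+1))` seconds, with the origin at the
#' `drug_start` marker when present (bins before drug start carry negative
#' indices); partial leading/trailing bins are dropped.
#'
#' @param trace a [flow_trace()]
#' @param origin_s bin origin, seconds; defaults to the `drug_start` marker,
#'   else the start of the trace
#' @return data frame with columns `minute`, `flow_mean`, `n_samples`
#' @export
minute_means <- function(trace, origin_s = NULL) {
  stopifnot(inherits(trace, "flow_trace"))
  origin_s <- origin_s %||% trace$markers$drug_start %||% min(trace$time_s)
  t0 <- min(trace$time_s); t1 <- max(trace$time_s)
  if (t1 - t0 < 60)
    stop_with("thrombolyzer_invalid_input", "trace spans less than one minute")
  dt <- stats::median(diff(trace$time_s))
  k_min <- ceiling((t0 - origin_s) / 60)
  k_max <- floor((t1 + dt - origin_s) / 60) - 1L
  ks <- seq(k_min, k_max)
  bin <- floor((trace$time_s - origin_s) / 60)
  keep <- bin >= k_min & bin <= k_max
  fm <- tapply(trace$flow[keep], factor(bin[keep], levels = ks), mean)
  ns <- tapply(trace$flow[keep], factor(bin[keep], levels = ks), length)
  data.frame(minute = ks, flow_mean = as.numeric(fm),
             n_samples = as.integer(ns))
}

#' Thrombolysis score
#'
#' The degree of flow restoration over the monitoring window:
#' `100 * mean flow during the 2 hours after drug start / baseline flow`.
#' The mean is the trapezoidal time-integral of the flow over
#' `[drug_start, drug_start + monitor_min]` divided by the window length,
#' with linear interpolation at the window boundaries.
#'
#' @param trace a [flow_trace()] with a `drug_start` marker
#' @param baseline baseline flow, ml/min
#' @param monitor_min monitoring window, minutes
#' @return score in percent (100 = full restoration to baseline)
#' @export
thrombolysis_score <- function(trace, baseline, monitor_min = 120) {
  stopifnot(inherits(trace, "flow_trace"))
  t_drug <- trace$markers$drug_start
  if (is.null(t_drug))
    stop_with("thrombolyzer_invalid_input", "trace has no `drug_start` marker")
  t_end <- t_drug + monitor_min * 60
  if (t_end > max(trace$time_s))
    stop_with("thrombolyzer_invalid_input",
              sprintf("trace ends %.1f s before the %g-minute window",
                      t_end - max(trace$time_s), monitor_min))
  inside <- trace$time_s > t_drug & trace$time_s < t_end
  xs <- c(t_drug, trace$time_s[inside], t_end)
  ys <- c(stats::approx(trace$time_s, trace$flow, xout = t_drug)$y,
          trace$flow[inside],
          stats::approx(trace$time_s, trace$flow, xout = t_end)$y)
  100 * trapz(xs, ys) / (t_end - t_drug) / baseline
}

#' Detect effective recanalization
#'
#' Effective recanalization is restoration of flow to at least `frac` of
#' baseline maintained for longer than `sustain_min` minutes. Operating on
#' minute means, this requires `sustain_min + 1` consecutive bins at or
#' above threshold (strictly greater than `sustain_min` minutes); the
#' reported time is the first such bin, i.e. the threshold-crossing minute
#' counted from drug start.
#'
#' @param trace a [flow_trace()] with a `drug_start` marker
#' @param baseline baseline flow, ml/min
#' @param frac flow threshold as a fraction of baseline
#' @param sustain_min minimum sustained duration, minutes (strict)
#' @return minutes from drug start to recanalization, or `NA` if not
#'   achieved
#' @export
detect_effective_recanalization <- function(trace, baseline, frac = 0.5,
                                            sustain_min = 30) {
  mm <- minute_means(trace)
  mm <- mm[mm$minute >= 0, ]
  need <- sustain_min + 1L
  ok <- mm$flow_mean >= frac * baseline
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values & r$lengths >= need
  if (!any(hit)) return(NA_real_)
  mm$minute[starts[which(hit)[1]]]
}

#' Detect reocclusion events
#'
#' Reocclusion after recanalization: runs of minute-mean flow below `frac`
#' of baseline sustained for at least `sustain_min` minutes, starting after
#' `after_min`. No numeric criterion for reocclusion accompanies the
#' recanalization definitions, so the 10\%-of-baseline / 2-minute rule here
#' mirrors the occlusion threshold on the minute-binned series.
#'
#' @param trace a [flow_trace()] with a `drug_start` marker
#' @param baseline baseline flow, ml/min
#' @param after_min only report events after this minute (typically the
#'   effective recanalization time)
#' @param frac flow threshold as a fraction of baseline
#' @param sustain_min minimum sustained duration, minutes
#' @return numeric vector of event start minutes (possibly empty)
#' @export
detect_reocclusion <- function(trace, baseline, after_min = 0, frac = 0.10,
                               sustain_min = 2) {
  mm <- minute_means(trace)
  mm <- mm[mm$minute >= 0, ]
  low <- mm$flow_mean < frac * baseline
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values & r$lengths >= sustain_min
  mins <- mm$minute[starts[hit]]
  mins[mins > after_min]
}

#' Full per-animal recanalization analysis
#'
#' Runs the whole scoring pipeline on one trace: per-animal minimum-flow
#' standardization, baseline estimation, complete-occlusion detection,
#' thrombolysis score, effective recanalization and reocclusion detection,
#' and the per-minute mean series.
#'
#' @param trace a [flow_trace()] with markers
#' @param monitor_min scoring window after drug start, minutes
#' @param frac,sustain_min effective recanalization thresholds
#' @param reocclusion_frac,reocclusion_sustain_min reocclusion thresholds
#' @param zero_frac occlusion threshold (fraction of baseline)
#' @param standardize apply [standardize_trace()] first
#' @param baseline_window_s baseline window length, seconds
#' @return an object of class `recanalization_report`
#' @export
analyze_flow_trace <- function(trace, monitor_min = 120, frac = 0.5,
                               sustain_min = 30, reocclusion_frac = 0.10,
                               reocclusion_sustain_min = 2,
                               zero_frac = 0.05, standardize = TRUE,
                               baseline_window_s = 300) {
  stopifnot(inherits(trace, "flow_trace"))
  if (isTRUE(standardize)) trace <- standardize_trace(trace)
  baseline <- compute_baseline(trace, window_s = baseline_window_s)
  occl <- detect_complete_occlusion(trace, baseline, zero_frac = zero_frac)
  score <- thrombolysis_score(trace, baseline, monitor_min = monitor_min)
  recan <- detect_effective_recanalization(trace, baseline, frac = frac,
                                           sustain_min = sustain_min)
  reocc <- if (!is.na(recan))
    detect_reocclusion(trace, baseline, after_min = recan,
                       frac = reocclusion_frac,
                       sustain_min = reocclusion_sustain_min)
  else numeric()
  structure(list(animal_id = trace$animal_id,
                 baseline_flow = baseline,
                 min_flow = min(trace$flow),
                 score_pct = score,
                 complete_occlusion_time_s = occl,
                 effective_recanalization_time_min = recan,
                 reocclusion_times_min = reocc,
                 minute_means = minute_means(trace),
                 params = list(monitor_min = monitor_min, frac = frac,
                               sustain_min = sustain_min,
                               reocclusion_frac = reocclusion_frac,
                               reocclusion_sustain_min = reocclusion_sustain_min,
                               zero_frac = zero_frac,
                               standardize = standardize)),
            class = "recanalization_report")
}

#' @export
print.recanalization_report <- function(x, ...) {
  cat(sprintf("<recanalization_report> %s\n", x$animal_id))
  cat(sprintf("  baseline %.3f ml/min, score %.2f%%\n",
              x$baseline_flow, x$score_pct))
  cat(sprintf("  complete occlusion at %s s; effective recanalization %s\n",
              format(x$complete_occlusion_time_s),
              if (is.na(x$effective_recanalization_time_min)) "not achieved"
              else sprintf("at %g min", x$effective_recanalization_time_min)))
  if (length(x$reocclusion_times_min))
    cat("  reocclusion at", paste(x$reocclusion_times_min, collapse = ", "),
        "min\n")
  invisible(x)
}
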