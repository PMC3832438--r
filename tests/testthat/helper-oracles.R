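# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (brute force / fine-grid) and share no code
# with the implementation paths they check.

# trace with a 5-minute baseline phase followed by piecewise-constant
# minute values; drug_start marks the start of the minute sequence
make_step_trace <- function(minute_flows, baseline = 1, dt = 1,
                            pre_min = 5, animal_id = "fixture") {
  t_drug <- pre_min * 60
  time_s <- seq(0, t_drug + length(minute_flows) * 60, by = dt)
  idx <- pmin(pmax(floor((time_s - t_drug) / 60) + 1L, 1L),
              length(minute_flows))
  flow <- ifelse(time_s < t_drug, baseline, minute_flows[idx])
  flow_trace(time_s, flow, animal_id = animal_id,
             markers = list(recording_start = 0, fecl3_on = 300,
                            drug_start = t_drug))
}

# brute-force scan over every contiguous sub-threshold run
occlusion_oracle <- function(time_s, flow, baseline, zero_frac = 0.05,
                             duration_s = 600) {
  below <- flow < zero_frac * baseline
  n <- length(time_s)
  dt_last <- if (n > 1) median(diff(time_s)) else 0
  i <- 1L
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1L]) j <- j + 1L
      end_t <- if (j < n) time_s[j + 1L] else time_s[n] + dt_last
      if (end_t - time_s[i] >= duration_s) return(time_s[i])
      i <- j + 1L
    } else i <- i + 1L
  }
  NA_real_
}

# fine-grid Riemann-sum version of the thrombolysis score
riemann_score <- function(trace, baseline, monitor_min = 120,
                          grid_dt = 0.05) {
  t0 <- trace$markers$drug_start
  grid <- seq(t0, t0 + monitor_min * 60, by = grid_dt)
  f <- approx(trace$time_s, trace$flow, xout = grid)$y
  100 * mean(f) / baseline
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual / expected - 1), rel_tol)
}
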