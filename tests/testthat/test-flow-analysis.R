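test_that("read_flow_trace validates structure and clips negatives", {
  d <- withr::local_tempdir()
  p <- file.path(d, "m1.csv")

  # round trip at 1 Hz
  tr <- make_step_trace(rep(1, 3))
  write_flow_trace(tr, p)
  back <- read_flow_trace(p, markers = file.path(d, "m1.json"))
  expect_equal(back$flow, tr$flow)
  expect_equal(back$markers$drug_start, 300)

  # negative flows are clipped with a reported count
  df <- data.frame(time_s = 0:9, flow = c(1, -0.1, 1, -0.2, -0.3, 1, 1, 1, 1, 1))
  write.csv(df, p, row.names = FALSE)
  expect_message(tr2 <- read_flow_trace(p), "3 negative")
  expect_equal(attr(tr2, "n_clipped"), 3)
  expect_equal(min(tr2$flow), 0)

  # distinct parse failures
  write.csv(data.frame(t = 1:3, f = 1:3), p, row.names = FALSE)
  expect_error(read_flow_trace(p), class = "thrombolyzer_missing_column")
  writeLines("time_s,flow", p)
  expect_error(read_flow_trace(p), class = "thrombolyzer_empty_file")
  write.csv(data.frame(time_s = c(0, 1, 2, 1.5, 3), flow = 1), p,
            row.names = FALSE)
  err <- tryCatch(read_flow_trace(p), error = identity)
  expect_s3_class(err, "thrombolyzer_nonmonotone_time")
  expect_match(conditionMessage(err), "row 4")
})

test_that("compute_baseline averages the pre-injury window", {
  tr <- make_step_trace(rep(0, 2), baseline = 1)
  expect_equal(compute_baseline(tr), 1)

  # linear ramp 0 -> 1 across exactly the window averages to ~0.5
  ramp <- flow_trace(0:299, seq(0, 1, length.out = 300),
                     markers = list(fecl3_on = 299))
  expect_equal(compute_baseline(ramp, window_s = 299, end_s = 299), 0.5,
               tolerance = 5e-3)

  # generated fixture: mean of the actual window samples, near the truth
  tr2 <- simulate_flow_trace(0, seed = 21)
  idx <- tr2$time_s < 300
  expect_equal(compute_baseline(tr2), mean(tr2$flow[idx]))
  expect_equal(compute_baseline(tr2), 0.8, tolerance = 0.01)

  expect_error(compute_baseline(tr2, window_s = 1e6),
               class = "thrombolyzer_invalid_input")
})

test_that("detect_complete_occlusion finds the first sustained zero-flow run", {
  # zero from 900 s to the end (> 600 s)
  time_s <- 0:2000
  flow <- ifelse(time_s < 900, 1, 0)
  tr <- flow_trace(time_s, flow)
  expect_equal(detect_complete_occlusion(tr, baseline = 1, from_s = 0), 900)

  # a 300 s run is not an occlusion
  flow2 <- ifelse(time_s >= 900 & time_s < 1200, 0, 1)
  expect_true(is.na(detect_complete_occlusion(flow_trace(time_s, flow2),
                                              baseline = 1, from_s = 0)))

  # two sub-threshold runs (400 s then 700 s): start of the second
  flow3 <- rep(1, length(time_s))
  flow3[time_s >= 100 & time_s < 500] <- 0
  flow3[time_s >= 800 & time_s < 1500] <- 0
  tr3 <- flow_trace(time_s, flow3)
  expect_equal(detect_complete_occlusion(tr3, baseline = 1, from_s = 0), 800)
  expect_equal(occlusion_oracle(time_s, flow3, 1), 800)
})

test_that("occlusion detector matches a brute-force scan on random fixtures", {
  set.seed(1234)
  for (k in 1:1000) {
    n <- sample(50:150, 1)
    time_s <- seq(0, by = 5, length.out = n)
    flow <- ifelse(runif(n) < 0.45, runif(n, 0, 0.04), runif(n, 0.2, 1))
    dur <- sample(c(20, 50, 100), 1)
    tr <- flow_trace(time_s, flow)
    expect_identical(
      detect_complete_occlusion(tr, baseline = 1, duration_s = dur,
                                from_s = 0),
      occlusion_oracle(time_s, flow, 1, duration_s = dur))
  }
})

test_that("standardize_trace maps the occluded level to zero", {
  tr <- flow_trace(0:10, c(5:0, 0:4) / 10 + 0.05)
  st <- standardize_trace(tr)
  expect_equal(min(st$flow), 0)
  expect_equal(attr(st, "offset"), 0.05)
  # already-zero minimum: unchanged
  tr0 <- flow_trace(0:10, c(5:0, 0:4) / 10)
  expect_equal(standardize_trace(tr0)$flow, tr0$flow)
  # ratio mode needs a positive minimum
  expect_error(standardize_trace(tr0, method = "ratio"),
               class = "thrombolyzer_invalid_input")
  expect_equal(min(standardize_trace(tr, method = "ratio")$flow), 1)
})

test_that("score after standardization matches the symbolic oracle", {
  tr <- simulate_flow_trace(2.5, seed = 31)
  st <- standardize_trace(tr)
  base <- compute_baseline(st)
  got <- thrombolysis_score(st, base)
  # oracle: apply the formula to the shifted samples on a fine grid
  shifted <- tr
  shifted$flow <- tr$flow - min(tr$flow)
  expect_rel_equal(got, riemann_score(shifted, base), 1e-3)
})

test_that("minute_means bins from drug start and drops partial bins", {
  tr <- make_step_trace(c(0.2, 0.4, 0.6), baseline = 1)
  mm <- minute_means(tr)
  expect_equal(mm$minute, -5:2)
  expect_equal(mm$flow_mean, c(rep(1, 5), 0.2, 0.4, 0.6))
  expect_true(all(mm$n_samples == 60))

  # 1 Hz: bin k equals the mean of samples 60k .. 60k+59
  tr2 <- simulate_flow_trace(5, seed = 41)
  mm2 <- minute_means(tr2)
  t0 <- tr2$markers$drug_start
  for (k in c(0, 7, 100)) {
    sel <- tr2$time_s >= t0 + 60 * k & tr2$time_s < t0 + 60 * (k + 1)
    expect_equal(mm2$flow_mean[mm2$minute == k], mean(tr2$flow[sel]))
  }

  # a 150-minute monitoring run yields 150 post-drug bins
  p150 <- flow_sim_params(post_drug_min = 150)
  tr3 <- simulate_flow_trace(0, params = p150, seed = 1)
  mm3 <- minute_means(tr3)
  expect_equal(sum(mm3$minute >= 0), 150)
})

test_that("thrombolysis score anchors: baseline-equal 100, zero 0, half 50", {
  tr <- make_step_trace(rep(1, 120), baseline = 1)
  expect_equal(thrombolysis_score(tr, 1), 100)
  expect_equal(thrombolysis_score(make_step_trace(rep(0, 120)), 1), 0)
  expect_equal(thrombolysis_score(make_step_trace(rep(0.5, 120)), 1), 50)
  expect_error(thrombolysis_score(make_step_trace(rep(1, 60)), 1),
               class = "thrombolyzer_invalid_input")
  noMark <- flow_trace(0:7200, rep(1, 7201))
  expect_error(thrombolysis_score(noMark, 1),
               class = "thrombolyzer_invalid_input")
})

test_that("trapezoidal score agrees with a fine Riemann oracle on seeded fixtures", {
  for (seed in c(5, 17)) {
    tr <- simulate_flow_trace(3.75, seed = seed)
    base <- compute_baseline(tr)
    expect_rel_equal(thrombolysis_score(tr, base),
                     riemann_score(tr, base), 1e-3)
  }
})

test_that("score and event times are invariant to flow rescaling", {
  tr <- simulate_flow_trace(5, regimen = regimen_total_bolus(5), seed = 13)
  rep1 <- analyze_flow_trace(tr)
  for (c_ in c(0.2, 37)) {
    scaled <- tr
    scaled$flow <- tr$flow * c_
    rep2 <- analyze_flow_trace(scaled)
    expect_equal(rep2$score_pct, rep1$score_pct)
    expect_equal(rep2$effective_recanalization_time_min,
                 rep1$effective_recanalization_time_min)
    expect_equal(rep2$reocclusion_times_min, rep1$reocclusion_times_min)
  }
})

test_that("effective recanalization needs strictly more than 30 sustained minutes", {
  # jump to 60% at minute 14 and stay: crossing time is 14
  flows <- c(rep(0, 14), rep(0.6, 106))
  expect_equal(detect_effective_recanalization(make_step_trace(flows), 1), 14)

  # 20-minute excursion then collapse: not effective
  flows2 <- c(rep(0, 14), rep(0.6, 20), rep(0, 86))
  expect_true(is.na(detect_effective_recanalization(make_step_trace(flows2), 1)))

  # exhaustive boundary: runs of 28..32 bins above threshold
  for (len in 28:32) {
    flows3 <- c(rep(0, 10), rep(0.7, len), rep(0, 120 - 10 - len))
    got <- detect_effective_recanalization(make_step_trace(flows3), 1)
    if (len >= 31) expect_equal(got, 10) else expect_true(is.na(got))
  }

  # when detected, at least 31 consecutive bins sit at/above 50% baseline
  tr <- simulate_flow_trace(5, seed = 3)
  st <- standardize_trace(tr)
  base <- compute_baseline(st)
  m <- detect_effective_recanalization(st, base)
  mm <- minute_means(st)
  sel <- mm$minute >= m & mm$minute < m + 31
  expect_true(all(mm$flow_mean[sel] >= 0.5 * base))
})

test_that("reocclusion detection honors threshold, sustain and ordering", {
  # never below 10% after recanalization: no events
  flows <- c(rep(0, 5), rep(0.8, 115))
  expect_length(detect_reocclusion(make_step_trace(flows), 1, after_min = 5), 0)

  # single-minute dip does not count; a 2-minute dip does
  dip1 <- c(rep(0.8, 50), 0.05, rep(0.8, 69))
  expect_length(detect_reocclusion(make_step_trace(dip1), 1, after_min = 0), 0)
  dip2 <- c(rep(0.8, 50), 0.05, 0.05, rep(0.8, 68))
  expect_equal(detect_reocclusion(make_step_trace(dip2), 1, after_min = 0), 50)

  # seed-fixed simulator property: total-dose bolus shows exactly one event
  tr <- simulate_flow_trace(5, regimen = regimen_total_bolus(5), seed = 1)
  rep <- analyze_flow_trace(tr)
  expect_length(rep$reocclusion_times_min, 1)
  expect_gt(rep$reocclusion_times_min,
            rep$effective_recanalization_time_min)
})
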