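# The simulators are first-class code: these tests pin their contracts
# (determinism, limiting behaviour, latent-state invariants), not just
# plausibility.

test_that("flow traces are seed-deterministic and untreated animals stay occluded", {
  a <- simulate_flow_trace(5, seed = 11)
  b <- simulate_flow_trace(5, seed = 11)
  expect_identical(a$flow, b$flow)
  expect_identical(a$time_s, b$time_s)
  c <- simulate_flow_trace(5, seed = 12)
  expect_false(identical(a$flow, c$flow))

  # vehicle control: no lysis drive, flow never rises above 10% of baseline
  # after occlusion and the thrombolysis score stays below 5%
  tr0 <- simulate_flow_trace(0, seed = 4)
  base <- compute_baseline(tr0)
  post <- tr0$time_s >= tr0$markers$occlusion_confirmed
  expect_true(all(tr0$flow[post] < 0.10 * base))
  expect_lt(thrombolysis_score(tr0, base), 5)
})

test_that("simulated traces carry a coherent experiment timeline", {
  tr <- simulate_flow_trace(5, seed = 2)
  m <- tr$markers
  expect_true(m$fecl3_on < m$fecl3_off)
  expect_true(m$occlusion_confirmed > m$fecl3_on)
  expect_equal(m$drug_start - m$occlusion_confirmed, 600)
  expect_gte(min(tr$flow), 0)
  # baseline phase is at least 5 minutes
  expect_gte(m$fecl3_on, 300)
})

test_that("thrombus burden stays in [0,1] for every step of seeded runs", {
  for (seed in 1:8) {
    dose <- c(0, 1, 2.5, 5, 10)[(seed %% 5) + 1]
    reg <- if (seed %% 2) NULL else regimen_total_bolus(dose)
    tr <- simulate_flow_trace(dose, regimen = reg, seed = seed)
    burden <- attr(tr, "sim_info")$burden
    expect_true(all(burden >= 0 & burden <= 1))
  }
})

test_that("an effective dose recanalizes without reocclusion under the canonical regimen", {
  tr <- simulate_flow_trace(5, seed = 1)
  rep <- analyze_flow_trace(tr)
  expect_false(is.na(rep$effective_recanalization_time_min))
  expect_length(rep$reocclusion_times_min, 0)
  expect_gt(rep$score_pct, 80)
})

test_that("mean score over 20 animals is non-decreasing in dose", {
  doses <- c(1, 1.75, 2.5, 3.75, 5, 10)
  means <- vapply(doses, function(d) {
    mean(vapply(1:20, function(k) {
      tr <- simulate_flow_trace(d, seed = 1000 * d + k)
      analyze_flow_trace(tr)$score_pct
    }, numeric(1)))
  }, numeric(1))
  expect_false(is.unsorted(means))
})

test_that("regimen ordering: total-dose bolus reoccludes, 10% bolus + infusion does not", {
  bolus <- analyze_flow_trace(
    simulate_flow_trace(5, regimen = regimen_total_bolus(5), seed = 1))
  inf <- analyze_flow_trace(
    simulate_flow_trace(5, regimen = regimen_fractional_bolus_infusion(5),
                        seed = 1))
  expect_length(bolus$reocclusion_times_min, 1)
  expect_length(inf$reocclusion_times_min, 0)
  expect_false(is.na(inf$effective_recanalization_time_min))
})

test_that("aggregometry simulator limiting behaviour", {
  p <- agg_sim_params()
  # dose 0: plateau reaches A_max within noise
  ctl <- simulate_aggregometry("aggregation", "ADP", 0, seed = 3)
  expect_equal(max_aggregation(ctl), p$a_max[["ADP"]], tolerance = 0.05)
  ctl_col <- simulate_aggregometry("aggregation", "collagen", 0, seed = 3)
  expect_equal(max_aggregation(ctl_col), p$a_max[["collagen"]],
               tolerance = 0.05)
  # full inhibition: flat at baseline
  flat <- simulate_aggregometry("aggregation", "ADP", Inf, seed = 3)
  expect_lt(max_aggregation(flat), 1)
  # infinite disaggregation rate: full restoration
  dis <- simulate_aggregometry("disaggregation", "ADP", Inf, seed = 3,
                               params = agg_sim_params(noise_sd = 0))
  expect_equal(percent_disaggregation(dis, 14), 100, tolerance = 1e-9)
  expect_error(simulate_aggregometry("melt", "ADP", 1))
  # determinism
  expect_identical(simulate_aggregometry("aggregation", "ADP", 1, seed = 9),
                   simulate_aggregometry("aggregation", "ADP", 1, seed = 9))
})

test_that("titration simulator: Langmuir midpoint, saturation, determinism", {
  concs <- c(1e-10, 1e-9, 1e-8, 1e-6)
  cv <- simulate_titration(1e-9, a_max = 2, concentrations = concs,
                           noise_sd = 0, seed = 1)
  expect_equal(cv$absorbance[2], 1)            # [L] = Kd -> a_max / 2
  expect_equal(cv$absorbance[4], 2, tolerance = 2e-3)  # [L] >> Kd -> a_max
  expect_identical(simulate_titration(1e-9, seed = 5),
                   simulate_titration(1e-9, seed = 5))
  expect_error(simulate_titration(-1), class = "thrombolyzer_invalid_input")
})

test_that("decay simulator: anchors and the serum sampling grid", {
  d <- simulate_decay(half_life_min = 4.1, noise_cv = 0, seed = 1)
  expect_equal(d$time_min, c(0, 5, 10, 20, 40, 80))
  expect_equal(d$fluorescence[1], 100)
  d2 <- simulate_decay(half_life_min = 7, times = c(0, 7), noise_cv = 0)
  expect_equal(d2$fluorescence[2], 50)
  expect_error(simulate_decay(4.1, times = numeric()),
               class = "thrombolyzer_invalid_input")
})

test_that("noiseless generator output lets the estimators recover truth to 1e-6", {
  cv <- simulate_titration(3.5e-9, a_max = 1.4,
                           concentrations = 10^seq(-11, -6, length.out = 10),
                           noise_sd = 0, seed = 1)
  fit <- fit_kd_linearization(cv, a_max = 1.4)
  expect_rel_equal(fit$kd, 3.5e-9, 1e-6)
  d <- simulate_decay(half_life_min = 4.1, noise_cv = 0, seed = 1)
  expect_rel_equal(fit_half_life(d)$half_life_min, 4.1, 1e-6)
})

test_that("simulators leave the caller's RNG stream untouched", {
  set.seed(99)
  expected <- rnorm(3)
  set.seed(99)
  invisible(simulate_flow_trace(2.5, seed = 7))
  invisible(simulate_titration(1e-9, seed = 7))
  expect_identical(rnorm(3), expected)
})
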