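# Langmuir oracle: independent nonlinear least-squares fit of
# A = a_max [L] / (Kd + [L]) using nls on log(Kd) for stability.
nls_langmuir_kd <- function(curve, kd_start) {
  df <- data.frame(L = curve$ligand_conc, A = curve$absorbance)
  fit <- stats::nls(A ~ amax * L / (exp(lkd) + L), data = df,
                    start = list(amax = max(df$A), lkd = log(kd_start)))
  exp(stats::coef(fit)[["lkd"]])
}

test_that("relative_saturation: midpoint, exclusion rule, closed form", {
  concs <- c(5e-10, 1e-9, 2e-9, 1e-8, 1e-6)
  cv <- simulate_titration(1e-9, a_max = 1, concentrations = concs,
                           noise_sd = 0)
  rs <- relative_saturation(cv, a_max = 1)
  expect_equal(rs$i[2], 0.5)                       # [L] = Kd
  expect_equal(rs$i, concs / (1e-9 + concs), tolerance = 1e-12)

  # a point at exactly a_max is singular and gets excluded
  cv2 <- titration_curve(c(1e-9, 1e-8, 1e-7), c(0.5, 0.9, 1.0))
  expect_message(rs2 <- relative_saturation(cv2, a_max = 1.0), "excluded 1")
  expect_equal(rs2$n_excluded, 1L)
  expect_false(rs2$usable[3])

  # plateau estimate: mean of the two highest-concentration absorbances
  rs3 <- relative_saturation(cv2)
  expect_equal(rs3$a_max, 0.95)
})

test_that("linearization is an exact identity on ideal data", {
  cv <- simulate_titration(1e-9, a_max = 1,
                           concentrations = 10^seq(-11, -6, length.out = 12),
                           noise_sd = 0)
  fit <- fit_kd_linearization(cv, a_max = 1)
  expect_rel_equal(fit$kd, 1e-9, 1e-9)
  expect_lt(abs(fit$intercept), 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-9)
})

test_that("three exact points recover the slope 1/Kd by hand algebra", {
  kd <- 2.5e-9
  # i = 1/3 at [L] = Kd/2, i = 1/2 at Kd, i = 2/3 at 2 Kd;
  # y = 1/(1-i) and x = [L]/i give y = x/Kd exactly
  L <- c(kd / 2, kd, 2 * kd)
  i <- L / (kd + L)
  cv <- titration_curve(L, i)          # absorbances with a_max = 1
  fit <- fit_kd_linearization(cv, a_max = 1)
  x <- L / i; y <- 1 / (1 - i)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_rel_equal(fit$slope, slope_hand, 1e-12)
  expect_rel_equal(fit$kd, kd, 1e-9)
})

test_that("noisy seed-fixed curve recovers Kd within 15%", {
  cv <- simulate_titration(6.8e-12, a_max = 1,
                           concentrations = 10^seq(-13, -9, length.out = 12),
                           noise_sd = 0.01, seed = 42)
  fit <- fit_kd_linearization(cv, a_max = 1)
  expect_rel_equal(fit$kd, 6.8e-12, 0.15)
})

test_that("linearization tracks a nonlinear Langmuir oracle across the reported affinities", {
  # the five integrin affinities reported for the disintegrin-Fc construct;
  # 24-point fixtures (a duplicate-well 12-point plate) so that both
  # estimators are precise enough for a 10% agreement band to be meaningful
  kds <- c(6.8e-12, 2.0e-11, 3.5e-9, 4.4e-9, 5.9e-9)
  for (k in seq_along(kds)) {
    kd <- kds[k]
    concs <- kd * 10^seq(-1.5, 2.5, length.out = 24)
    cv <- simulate_titration(kd, a_max = 1, concentrations = concs,
                             noise_sd = 0.01, seed = 500 + k)
    lin <- fit_kd_linearization(cv, a_max = 1)
    oracle <- nls_langmuir_kd(cv, kd_start = kd * 2)
    expect_rel_equal(lin$kd, oracle, 0.10)
  }
})

test_that("Kd is invariant to rescaling the absorbance units", {
  cv <- simulate_titration(2e-11, a_max = 1,
                           concentrations = 10^seq(-12, -8, length.out = 12),
                           noise_sd = 0.01, seed = 9)
  f1 <- fit_kd_linearization(cv, a_max = 1)
  scaled <- titration_curve(cv$ligand_conc, cv$absorbance * 250)
  f2 <- fit_kd_linearization(scaled, a_max = 250)
  expect_rel_equal(f2$kd, f1$kd, 1e-9)
})

test_that("fit failures are classed errors", {
  # too few usable points
  cv <- titration_curve(c(1e-9, 1e-8), c(0.3, 0.6))
  expect_error(fit_kd_linearization(cv, a_max = 1),
               class = "thrombolyzer_fit_error")
  # decreasing absorbance: negative slope
  bad <- titration_curve(10^seq(-10, -8, length.out = 6),
                         seq(0.8, 0.3, length.out = 6))
  expect_error(fit_kd_linearization(bad, a_max = 1),
               class = "thrombolyzer_fit_error")
})

test_that("half-life fit: exact grid recovery and two-point closed form", {
  d <- simulate_decay(half_life_min = 4.1, noise_cv = 0)
  fit <- fit_half_life(d)
  expect_rel_equal(fit$half_life_min, 4.1, 1e-9)

  # halving per step of a unit grid
  d2 <- decay_curve(c(0, 1, 2), c(100, 50, 25))
  expect_rel_equal(fit_half_life(d2)$half_life_min, 1, 1e-12)

  # exactly two points: equals the closed-form solution
  d3 <- decay_curve(c(3, 11), c(80, 14))
  closed <- log(2) * (11 - 3) / log(80 / 14)
  expect_warning(fit3 <- fit_half_life(d3), "2 points")
  expect_rel_equal(fit3$half_life_min, closed, 1e-12)

  expect_error(decay_curve(c(0, 5), c(1, -1)),
               class = "thrombolyzer_invalid_input")
  expect_error(fit_half_life(decay_curve(c(0, 5, 10), c(1, 2, 3))),
               class = "thrombolyzer_fit_error")
})

test_that("noisy decay estimates average within 5% of truth", {
  est <- vapply(1:10, function(s)
    fit_half_life(simulate_decay(4.1, noise_cv = 0.02,
                                 seed = s))$half_life_min,
    numeric(1))
  expect_rel_equal(mean(est), 4.1, 0.05)
})
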