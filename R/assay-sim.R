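#' Aggregometry simulator parameters
#'
#' Kinetic and dose-response constants of the impedance aggregometry
#' simulator. Plateau impedances default to the maximal control aggregations
#' observed with the two agonists (16 ohms for 20 uM ADP, 22 ohms for
#' 5 ug/ml collagen). Inhibition of aggregation follows a Hill curve
#' `I(dose) = dose^h / (dose^h + ic50^h)`; disaggregation of a preformed
#' aggregate is exponential toward baseline with a dose-dependent rate
#' `k_dis(dose) = k_ref * (dose / ref_dose)^exponent`. The rate constants
#' were calibrated against the printed restoration percentages (ADP
#' aggregates resolve within seconds, collagen aggregates over minutes).
#'
#' @param a_max named plateau impedances (ohms) per agonist
#' @param k_a aggregation rise rate, per second
#' @param ic50 named half-inhibitory doses (ug) per agonist
#' @param inh_hill named Hill coefficients of the inhibition curve
#' @param dis_k_ref named disaggregation rate (per second) at `dis_ref_dose`
#' @param dis_ref_dose reference dose for the disaggregation rate, ug
#' @param dis_exponent named power-law exponent of rate vs dose
#' @param agonist_time_s agonist addition time, seconds
#' @param addition_time_s test-agent addition time in disaggregation mode,
#'   seconds (after maximal aggregation is reached)
#' @param duration_s recording length, seconds
#' @param noise_sd additive impedance noise, ohms
#' @return an object of class `agg_sim_params`
#' @export
agg_sim_params <- function(a_max = c(ADP = 16, collagen = 22),
                           k_a = 0.02,
                           ic50 = c(ADP = 0.1, collagen = 2.9),
                           inh_hill = c(ADP = 1.5, collagen = 1),
                           dis_k_ref = c(ADP = 0.0123, collagen = 3.6e-4),
                           dis_ref_dose = 10,
                           dis_exponent = c(ADP = 1, collagen = 0.3),
                           agonist_time_s = 30, addition_time_s = 360,
                           duration_s = 720, noise_sd = 0.15) {
  structure(list(a_max = a_max, k_a = k_a, ic50 = ic50, inh_hill = inh_hill,
                 dis_k_ref = dis_k_ref, dis_ref_dose = dis_ref_dose,
                 dis_exponent = dis_exponent, agonist_time_s = agonist_time_s,
                 addition_time_s = addition_time_s, duration_s = duration_s,
                 noise_sd = noise_sd),
            class = "agg_sim_params")
}

#' Simulate an impedance aggregometry trace
#'
#' In `aggregation` mode the test agent is present from the start and the
#' impedance rises as `a_max * (1 - I(dose)) * (1 - exp(-k_a t))` after
#' agonist addition. In `disaggregation` mode a control aggregate forms
#' first; the test agent is added at `addition_time_s` and the impedance
#' decays exponentially toward baseline at the dose-dependent rate.
#'
#' @param mode `"aggregation"` or `"disaggregation"`
#' @param agonist `"ADP"` or `"collagen"`
#' @param dose test-agent amount, ug (may be `Inf` to probe the limiting
#'   behaviour)
#' @param params an [agg_sim_params()]
#' @param seed integer seed
#' @return an [agg_trace()]
#' @export
simulate_aggregometry <- function(mode = c("aggregation", "disaggregation"),
                                  agonist = c("ADP", "collagen"),
                                  dose = 0, params = agg_sim_params(),
                                  seed = 1) {
  mode <- match.arg(mode)
  agonist <- match.arg(agonist)
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0)
    stop_with("thrombolyzer_invalid_input", "`dose` must be a single number >= 0")
  p <- params
  time_s <- seq(0, p$duration_s)
  amax <- p$a_max[[agonist]]
  t_ag <- p$agonist_time_s

  if (mode == "aggregation") {
    h <- p$inh_hill[[agonist]]
    inh <- if (is.infinite(dose)) 1 else
      dose^h / (dose^h + p$ic50[[agonist]]^h)
    a <- ifelse(time_s <= t_ag, 0,
                amax * (1 - inh) * (1 - exp(-p$k_a * (time_s - t_ag))))
    t_add <- NULL
  } else {
    t_add <- p$addition_time_s
    rise <- ifelse(time_s <= t_ag, 0,
                   amax * (1 - exp(-p$k_a * (time_s - t_ag))))
    a_add <- amax * (1 - exp(-p$k_a * (t_add - t_ag)))
    k_dis <- p$dis_k_ref[[agonist]] *
      (dose / p$dis_ref_dose)^p$dis_exponent[[agonist]]
    decay <- a_add * exp(-k_dis * (time_s - t_add))
    decay[!is.finite(decay)] <- 0  # infinite rate: instant return to baseline
    a <- ifelse(time_s <= t_add, rise, decay)
  }
  imp <- with_seed(seed, a + stats::rnorm(length(a), 0, p$noise_sd))
  agg_trace(time_s, imp, agonist = agonist, treatment_dose = dose,
            addition_time_s = t_add, agonist_time_s = t_ag)
}

#' Simulate a one-site ELISA titration
#'
#' Absorbances follow a Langmuir isotherm
#' `A([L]) = a_max * [L] / (Kd + [L])` with additive Gaussian noise. The
#' default concentration grid spans the sub-picomolar to ~100 nM range used
#' when titrating the Fc-tagged ligand against immobilized integrins.
#'
#' @param kd ground-truth dissociation constant, molar (> 0)
#' @param a_max saturation absorbance
#' @param concentrations ligand concentrations, molar, all positive
#' @param noise_sd additive absorbance noise (same units as `a_max`)
#' @param seed integer seed
#' @return a [titration_curve()]; attribute `truth` records `kd` and `a_max`
#' @export
simulate_titration <- function(kd, a_max = 1,
                               concentrations = 10^seq(-13, -7,
                                                       length.out = 12),
                               noise_sd = 0.01, seed = 1) {
  assert_scalar_num(kd, "kd", 0, strict_lower = TRUE)
  if (any(concentrations <= 0))
    stop_with("thrombolyzer_invalid_input", "concentrations must be positive")
  a <- a_max * concentrations / (kd + concentrations)
  a <- with_seed(seed, a + stats::rnorm(length(a), 0, noise_sd))
  curve <- titration_curve(concentrations, a)
  attr(curve, "truth") <- list(kd = kd, a_max = a_max)
  curve
}

#' Simulate a mono-exponential fluorescence decay
#'
#' `F(t) = f0 * 2^(-t / half_life) * (1 + eps)` with multiplicative Gaussian
#' noise, sampled by default on the serum collection grid 0, 5, 10, 20, 40
#' and 80 minutes.
#'
#' @param half_life_min ground-truth half-life, minutes (> 0)
#' @param times sampling times, minutes (non-empty)
#' @param f0 fluorescence at time zero
#' @param noise_cv multiplicative noise coefficient of variation
#' @param seed integer seed
#' @return a [decay_curve()]
#' @export
simulate_decay <- function(half_life_min = 4.1,
                           times = c(0, 5, 10, 20, 40, 80),
                           f0 = 100, noise_cv = 0.02, seed = 1) {
  assert_scalar_num(half_life_min, "half_life_min", 0, strict_lower = TRUE)
  if (length(times) == 0L)
    stop_with("thrombolyzer_invalid_input", "`times` must be non-empty")
  f <- f0 * 2^(-times / half_life_min)
  f <- with_seed(seed, f * (1 + stats::rnorm(length(times), 0, noise_cv)))
  decay_curve(times, f)
}
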