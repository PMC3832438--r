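#' One-compartment pharmacokinetic parameters
#'
#' Elimination is first order with rate constant \eqn{k_{el}}; the half-life
#' is \eqn{t_{1/2} = \ln 2 / k_{el}}. Exactly one of `half_life_min` or
#' `k_el` must be supplied, the other is derived. The default half-life of
#' 4.1 minutes is the serum half-life of the disintegrin measured by
#' rhodamine fluorescence in mice.
#'
#' @param half_life_min elimination half-life in minutes
#' @param k_el elimination rate constant, per minute
#' @return an object of class `pk_params` with fields `k_el` and
#'   `half_life_min`
#' @examples
#' pk_params(half_life_min = 4.1)
#' @export
pk_params <- function(half_life_min = NULL, k_el = NULL) {
  if (is.null(half_life_min) == is.null(k_el))
    stop_with("thrombolyzer_invalid_input",
              "supply exactly one of `half_life_min` or `k_el`")
  if (is.null(k_el)) {
    assert_scalar_num(half_life_min, "half_life_min", 0, strict_lower = TRUE)
    k_el <- log(2) / half_life_min
  } else {
    assert_scalar_num(k_el, "k_el", 0, strict_lower = TRUE)
    half_life_min <- log(2) / k_el
  }
  structure(list(k_el = k_el, half_life_min = half_life_min),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> k_el = %.4g /min (t1/2 = %.3g min)\n",
              x$k_el, x$half_life_min))
  invisible(x)
}

#' Dosing regimen: boluses plus a zero-order infusion
#'
#' A fraction `bolus_fraction` of `total_dose` is given as `n_boluses`
#' equal IV boluses at `bolus_times_min`; the remainder is infused at a
#' constant rate over `infusion_duration_min`, starting at time 0. The
#' default regimen (10\% bolus, remainder infused over 60 minutes) is the
#' administration method that achieved effective recanalization without
#' reocclusion.
#'
#' @param total_dose total dose, mg/kg
#' @param bolus_fraction fraction of the total dose given as bolus(es), in
#'   \[0, 1\]
#' @param n_boluses number of equal boluses
#' @param bolus_times_min sorted, non-negative bolus times in minutes
#' @param infusion_duration_min infusion duration in minutes (0 = no
#'   infusion; then `bolus_fraction` must be 1)
#' @return an object of class `dose_regimen`
#' @export
dose_regimen <- function(total_dose, bolus_fraction = 0.1, n_boluses = 1L,
                         bolus_times_min = 0, infusion_duration_min = 60) {
  assert_scalar_num(total_dose, "total_dose", 0)
  assert_scalar_num(bolus_fraction, "bolus_fraction", 0, 1)
  assert_scalar_num(infusion_duration_min, "infusion_duration_min", 0)
  if (length(bolus_times_min) != n_boluses)
    stop_with("thrombolyzer_invalid_input",
              "`bolus_times_min` must have one entry per bolus")
  if (any(bolus_times_min < 0) || is.unsorted(bolus_times_min))
    stop_with("thrombolyzer_invalid_input",
              "`bolus_times_min` must be sorted and non-negative")
  if (bolus_fraction < 1 && infusion_duration_min <= 0)
    stop_with("thrombolyzer_invalid_input",
              "bolus_fraction < 1 requires a positive infusion duration")
  structure(list(total_dose = total_dose, bolus_fraction = bolus_fraction,
                 n_boluses = as.integer(n_boluses),
                 bolus_times_min = as.numeric(bolus_times_min),
                 infusion_duration_min = infusion_duration_min),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf(
    "<dose_regimen> %.3g mg/kg: %d bolus(es) of %.3g mg/kg at t = {%s} min",
    x$total_dose, x$n_boluses,
    x$total_dose * x$bolus_fraction / x$n_boluses,
    paste(x$bolus_times_min, collapse = ", ")))
  if (x$bolus_fraction < 1)
    cat(sprintf(" + %.3g mg/kg infused over %g min",
                x$total_dose * (1 - x$bolus_fraction), x$infusion_duration_min))
  cat("\n")
  invisible(x)
}

#' Canonical administration regimens
#'
#' The four administration methods compared at a fixed total dose:
#' single bolus of the total dose; double bolus (half the dose at 0 and 60
#' minutes); half-dose bolus plus 60-minute infusion of the remainder; and
#' 10\% bolus plus 60-minute infusion of the remainder.
#'
#' @param total_dose total dose, mg/kg
#' @name regimens
NULL

#' @rdname regimens
#' @export
regimen_total_bolus <- function(total_dose)
  dose_regimen(total_dose, bolus_fraction = 1, infusion_duration_min = 0)

#' @rdname regimens
#' @export
regimen_double_bolus <- function(total_dose)
  dose_regimen(total_dose, bolus_fraction = 1, n_boluses = 2L,
               bolus_times_min = c(0, 60), infusion_duration_min = 0)

#' @rdname regimens
#' @export
regimen_half_bolus_infusion <- function(total_dose)
  dose_regimen(total_dose, bolus_fraction = 0.5)

#' @rdname regimens
#' @export
regimen_fractional_bolus_infusion <- function(total_dose)
  dose_regimen(total_dose, bolus_fraction = 0.1)

#' Plasma concentration under a one-compartment model
#'
#' Superposition of first-order bolus decay and zero-order infusion with
#' first-order elimination. The volume of distribution is normalized to 1,
#' so concentrations are in dose units (mg/kg): a bolus of amount \eqn{D} at
#' time \eqn{t_0} contributes \eqn{D e^{-k_{el}(t - t_0)}} for
#' \eqn{t \ge t_0}; an infusion of amount \eqn{A} over duration \eqn{T}
#' contributes \eqn{\frac{A}{T k_{el}}(1 - e^{-k_{el} t})} while running and
#' decays exponentially afterwards.
#'
#' @param regimen a [dose_regimen()]
#' @param t time(s) in minutes since the start of administration; must be
#'   non-negative
#' @param pk a [pk_params()]
#' @return numeric vector of concentrations, same length as `t`
#' @examples
#' pk <- pk_params(half_life_min = 4.1)
#' reg <- regimen_total_bolus(1)
#' pk_concentration(reg, 4.1, pk)  # half the bolus remains
#' @export
pk_concentration <- function(regimen, t, pk) {
  stopifnot(inherits(regimen, "dose_regimen"), inherits(pk, "pk_params"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop_with("thrombolyzer_invalid_input", "`t` must be finite numeric")
  if (any(t < 0))
    stop_with("thrombolyzer_invalid_input", "`t` must be non-negative")
  k <- pk$k_el
  conc <- numeric(length(t))
  bolus_amt <- regimen$total_dose * regimen$bolus_fraction / regimen$n_boluses
  if (bolus_amt > 0) {
    for (t0 in regimen$bolus_times_min) {
      dt <- t - t0
      conc <- conc + ifelse(dt >= 0, bolus_amt * exp(-k * dt), 0)
    }
  }
  inf_amt <- regimen$total_dose * (1 - regimen$bolus_fraction)
  if (inf_amt > 0 && regimen$infusion_duration_min > 0) {
    T_ <- regimen$infusion_duration_min
    rate <- inf_amt / T_
    cT <- (rate / k) * (1 - exp(-k * T_))
    conc <- conc + ifelse(t <= T_,
                          (rate / k) * (1 - exp(-k * t)),
                          cT * exp(-k * (t - T_)))
  }
  conc
}
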