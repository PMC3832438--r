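---
title: "Scoring thrombolysis from carotid flow traces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring thrombolysis from carotid flow traces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombolyzer)
```

## The measurement problem

In the ferric-chloride (FeCl3) carotid thrombosis model, a filter paper
soaked in FeCl3 is applied to the exposed common carotid artery (CCA) of a
mouse. Oxidative injury triggers a platelet-rich thrombus; a Doppler probe
records blood flow continuously. A thrombolytic agent — here a
disintegrin, an RGD-motif snake-venom protein that blocks platelet
integrins, chiefly GP IIb/IIIa (integrin alpha2b-beta3) — is given
intravenously ten minutes after the artery has occluded, and the degree
and durability of flow restoration over the following two hours quantifies
its efficacy.

`thrombolyzer` implements the whole quantitative chain: event detection
and scoring on flow traces, the companion in-vitro statistics (impedance
aggregometry, ELISA binding affinity, serum half-life), group summaries
and comparisons, and a simulator that generates every input type with the
kinetic structure the analyses assume. Because no raw recordings from such
experiments are deposited anywhere, the simulator is the package's
testing ground: it defines a *stated world* in which every detector and
estimator can be checked against ground truth.

## Flow-trace analysis

**Baseline.** The mean flow over the 5 minutes preceding FeCl3
application (`compute_baseline()`). All event thresholds are expressed as
fractions of this per-animal baseline, which makes every statistic
invariant to rescaling the flow units — a property the test suite asserts.

**Standardization.** Measured flows are standardized by the per-animal
minimum. The package subtracts the minimum (mapping the occluded plateau
to zero) rather than dividing by it: division is numerically explosive
when the occluded flow is near zero, and subtraction preserves the score's
scale invariance. Division is still available via
`standardize_trace(method = "ratio")` for comparison.

**Complete occlusion** is absence of flow for 10 minutes. Since a Doppler
instrument never reads exactly zero, "absence" is flow below 5% of
baseline (configurable); `detect_complete_occlusion()` returns the start
of the first contiguous sub-threshold run lasting at least 600 s. The
implementation is checked against a brute-force scan over every run on a
thousand randomized fixtures.

**Thrombolysis score.** The primary endpoint:
100 x (mean flow during the 2-hour monitoring window) / (baseline flow),
with the mean computed as a trapezoidal time-integral divided by the
window length, so irregular sampling is handled correctly. The per-animal
baseline is used as the denominator: the alternative reading (a control
group's mean baseline) would break scale invariance and self-consistency.

**Effective recanalization** is restoration to at least 50% of baseline
maintained for *longer than* 30 minutes. All temporal analyses operate on
minute-binned means (`minute_means()`, bins anchored at drug start), so
the criterion is 31 consecutive qualifying bins — "longer than 30" is
read strictly, and a single sub-threshold bin breaks a run (no dip
tolerance). The reported time is the threshold-crossing minute, not the
end of the confirmation window: published times to recanalization of
about 3 minutes under a full-dose bolus are only consistent with the
crossing-time convention.

**Reocclusion** has no published numeric criterion (figures simply mark
arrows where flow collapses). The package mirrors the occlusion rule on
minute bins: minute-mean flow below 10% of baseline sustained for at
least 2 minutes, occurring after effective recanalization.

**Group statistics.** `summarize_doses()` reports per-group mean and
sample SD (n − 1); `compare_groups()` applies one-way ANOVA with Tukey
HSD contrasts (three or more groups) or the exact Mann-Whitney U test
(two groups), with 0.05 as the significance threshold and p = 1 by
convention for fully degenerate input.

## The simulator

The generator replaces the animal experiment with a one-state
pharmacodynamic model. The latent thrombus burden $B \in [0,1]$
(1 = fully occlusive) evolves as

$$\frac{dB}{dt} = -k_{lysis}\,E(t)\,B \;+\; k_{regrowth}\,
  \mathbf{1}[C_{eq}(t) < c_{crit}]\,B(1-B),$$

integrated by explicit Euler at the 1 s sampling step (a warning fires if
a step would leave $[0,1]$ by more than 1e-6 before clipping). Observed
flow is $\text{baseline} \times (1-B)(1+\varepsilon)$ with multiplicative
noise $\varepsilon \sim N(0, 0.05)$ plus a small additive instrument
floor (SD 1% of baseline), clipped at zero.

The lysis drive is a Hill function
$E = e_{max} C_{eq}^h / (C_{eq}^h + EC_{50}^h)$ of the plasma
concentration from a one-compartment model (`pk_concentration()`):
first-order elimination with the measured 4.1-minute serum half-life,
boluses superposed with zero-order infusions, volume of distribution
normalized to 1. Concentrations are expressed as *dose equivalents*
$C_{eq} = C/c_{ref}$, where $c_{ref}$ is the plateau concentration per
unit dose under the canonical regimen (10% bolus + 60-minute infusion),
so `ec50` and the regrowth gate `conc_crit` are in mg/kg equivalents.

Regrowth is gated by the concentration falling below `conc_crit` rather
than varying continuously — this reproduces the *abrupt* reocclusions
seen when a bolus washes out. The logistic form $B(1-B)$ means a thrombus
driven very low regrows only slowly, which is exactly why a sustained
infusion prevents reocclusion within the monitoring window while an
equally dosed single bolus does not: the infusion holds the lysis drive
up for an hour and leaves $B \sim 10^{-4}$, whereas the bolus stops
lysing after ~20 minutes from $B \approx 0.1$.

### Calibration and its limits

Defaults (`ec50 = 3.5` mg/kg, `hill = 7`, `k_lysis = 0.15`/min,
`k_regrowth = 0.09`/min, `conc_crit = 1`) were fixed once, before the
test suite was written, by matching the deterministic dose-response to
the published group means under the canonical regimen: near-zero
restoration at and below 1.75 mg/kg, roughly 30% at 2.5 mg/kg, and
near-baseline (~94%) at 5 and 10 mg/kg, together with the qualitative
regimen ordering (total-dose bolus reoccludes at roughly 70–100 minutes;
10% bolus + infusion does not). A shallower Hill coefficient of ~4 was
considered and rejected: no lysis rate then keeps 1.75 mg/kg near zero
while 5 mg/kg reaches baseline.

One published mean is deliberately not reproduced: 60.5 ± 38.8% at
3.75 mg/kg. That group was a bimodal mix (three of five animals
recanalized), and a deterministic single-state burden model cannot land
its mean on the steep part of the curve without violating the anchors
above; the simulator yields ~89% there. Tests therefore assert the
monotone trend and the named anchors, not the 3.75 mg/kg mean.

Inter-animal variability is a lognormal multiplier on `k_lysis`
(mean 1, scale `lysis_cv = 0.15`): enough spread to make group SDs and
standard errors meaningful without destroying the ordering of group
means. Because the published 5 and 10 mg/kg means are nearly tied
(94.50 vs 94.94%), strict ordering of those two groups is only asserted
at n = 20 per dose; a five-animal mean cannot resolve a 0.4-point gap.

What a green test does **not** establish: the simulator models no FeCl3
chemistry, endothelial biology, platelet signaling, spontaneous
recanalization, or multi-compartment kinetics, and its noise is
stationary Gaussian — real Doppler traces carry cardiac pulsatility,
probe drift and motion artifacts. Green tests establish that the
*analysis* recovers what the *stated world* put in, not that the world
is faithful.

### Other generators

* `simulate_aggregometry()` — impedance rises to the agonist's maximal
  control aggregation (16 ohms for 20 uM ADP, 22 ohms for 5 ug/ml
  collagen) scaled by a Hill inhibition curve; in disaggregation mode a
  preformed aggregate decays exponentially toward baseline at a
  dose-dependent rate calibrated to the printed restoration percentages
  (ADP aggregates resolve in seconds, collagen in minutes).
* `simulate_titration()` — one-site Langmuir absorbances with additive
  noise; `simulate_decay()` — mono-exponential fluorescence on the serum
  sampling grid 0, 5, 10, 20, 40, 80 minutes with multiplicative noise.
  On noiseless output the estimators recover truth to 1e-6 relative, a
  pinned invariant.

All generators take explicit integer seeds, never touch the global RNG
stream, and are bitwise-reproducible. Study orchestration
(`run_study()`) derives per-animal seeds as
`seed_base + hash(group, index)` so extending a design never perturbs
existing animals.

## Binding affinity: the linearization and its numerics

For one-site binding with relative saturation $i = A/A_{max}$, the plot
of $1/(1-i)$ against $[L]/i$ is a straight line of slope $1/K_d$ — an
exact algebraic identity with zero intercept for ideal Langmuir data.
`fit_kd_linearization()` fits by ordinary least squares with a *free*
intercept $b$: the source material writes the line with an intercept
term, and although ideal data force $b = 0$, estimating it surfaces
model misfit instead of hiding it.

Two numerical choices matter:

* **Saturation window.** The variance of $1/(1-i)$ grows as
  $(1-i)^{-4}$, so points near saturation dominate and destabilize an
  unweighted fit; at the other end, $[L]/i$ for nearly unbound points is
  noise-dominated. At the 1% absorbance noise typical of an ELISA, an
  unrestricted fit lands within 15% of truth in barely a sixth of random
  runs. Restricting the fit to points with $0.05 \le i \le 0.85$
  (chosen by variance analysis and Monte-Carlo before the tests were
  frozen) makes recovery nearly unbiased, with ~94% of runs within 15%
  for both reported high-affinity constants (6.8e-12 and 2.0e-11 M).
  The window is a parameter (`i_window`); points outside it are kept in
  the object but not fitted. Ideal data are unaffected — the identity
  holds on whatever points remain.
* **Exclusion, not clamping.** Points with $i \ge 1$ or $i \le 0$
  (possible under noise once $A_{max}$ is estimated) are singular in the
  transform and are excluded with a logged count; clamping them would
  bias the slope.

$A_{max}$ defaults to the mean absorbance at the two highest
concentrations (the top plateau); a known value can be supplied, and the
synthetic world always knows its own. Whether the original fits shared a
saturation estimate across integrins is not stated; fits here are
per-curve and independent.

## Half-life

`fit_half_life()` regresses $\ln F$ on time; $k_{el} = -\text{slope}$,
$t_{1/2} = \ln 2 / k_{el}$. With exactly two points this reduces to the
closed-form solution (asserted); non-positive fluorescence and
non-decaying series are classed errors. On the serum grid with 2%
multiplicative noise, the mean estimate over 10 seeds recovers the
4.1-minute truth within 5%.

## Degenerate inputs and tie-breaks

* Flow traces: strictly increasing time is enforced at construction;
  parse errors are classed (`thrombolyzer_missing_column`,
  `thrombolyzer_empty_file`, `thrombolyzer_nonmonotone_time`) and name
  the offending row. Negative flows are clipped to zero on read, with a
  count.
* A sample at $t_i$ covers $[t_i, t_{i+1})$; the final sample extends by
  the median sampling interval. Minute bins are half-open and partial
  bins are dropped.
* `percent_inhibition()` reports enhancement (negative values) with a
  warning rather than clamping; an all-baseline aggregometry trace has
  maximal aggregation 0, and the disaggregation statistic is an error
  when no aggregate formed (denominator zero).
* ANOVA on groups with zero variance everywhere returns p = 1 by stated
  convention; otherwise the usual machinery runs.

## Worked example

```{r example, eval = FALSE}
tr <- simulate_flow_trace(5, seed = 1)        # 5 mg/kg, canonical regimen
analyze_flow_trace(tr)
#> <recanalization_report> sim
#>   baseline 0.801 ml/min, score 92.92%
#>   complete occlusion at 708 s; effective recanalization at 5 min

rep <- run_study(dose_response_design(n_per_group = 5, seed_base = 1))
rep
#> <study_report> 35 animals in 7 groups ...
#>   saline      n=5  score  0.40 +/- 0.01%  recanalized 0/5
#>   ...
#>   5 mg/kg     n=5  score 93.39 +/- 0.99%  recanalized 5/5
```

## Known limitations

* The instrument sampling rate is undocumented in the source material;
  1 Hz is assumed (configurable via `sample_dt_s`).
* The simulator's dose-response is deterministic-unimodal per animal; it
  cannot generate the bimodal recanalize-or-not mixtures that inflate
  published group SDs at intermediate doses.
* The aged-thrombus design is a pure parameter preset (lysis rate
  decaying with thrombus age); no fibrin cross-linking biology is
  modeled.
* The CLI reads JSON configuration only (no YAML dependency).
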