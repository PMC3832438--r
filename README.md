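# thrombolyzer

Quantitative assessment of thrombolytic efficacy in the FeCl3-induced
carotid arterial thrombosis model, for preclinical pharmacology work on
platelet-directed thrombolytics (disintegrins and other GP IIb/IIIa
antagonists).

In this model a mouse carotid artery is injured with ferric chloride,
occludes with a platelet-rich thrombus, and a candidate thrombolytic is
infused while a Doppler probe records blood flow. The package turns those
recordings — and the companion in-vitro assays — into the field's standard
statistics:

* **Thrombolysis score**: `100 × (mean flow over the 2-h monitoring
  window) / (baseline flow)`, per animal, trapezoid-integrated, after
  per-animal minimum-flow standardization.
* **Event detection** on minute-binned flow: complete occlusion (flow
  < 5% of baseline sustained 10 min), effective recanalization (≥ 50% of
  baseline sustained > 30 min, crossing time reported), reocclusion
  (< 10% sustained ≥ 2 min after recanalization).
* **Aggregometry statistics**: percent inhibition `100(1 − a/a0)` from
  maximal impedance aggregations, and percent disaggregation of preformed
  aggregates relative to the pre-agonist baseline.
* **Binding affinity**: Kd from ELISA titrations via the linearization
  `1/(1−i) = ([L]/i)/Kd − b` (slope = 1/Kd), with a variance-motivated
  usable-saturation window.
* **Half-life**: log-linear fit of fluorescence decay,
  `t1/2 = ln 2 / k_el`.
* **Group statistics**: mean ± SD summaries, one-way ANOVA + Tukey HSD,
  exact Mann-Whitney for two groups.
* **A PK-driven simulator** for every input type: one-compartment
  bolus + infusion pharmacokinetics coupled to a latent thrombus-burden
  ODE (`dB/dt = −k_lysis·E(C)·B + k_regrowth·[C < c_crit]·B(1−B)`),
  Langmuir titrations, mono-exponential decays, aggregometry kinetics —
  all seed-deterministic. Since no raw recordings of this kind are
  publicly deposited, the simulator is what makes the whole analysis
  chain testable against known ground truth.

## Worked example

```r
library(thrombolyzer)

# one animal: 5 mg/kg, 10% bolus + 60-min infusion of the remainder
tr <- simulate_flow_trace(5, seed = 1)
analyze_flow_trace(tr)
#> <recanalization_report> sim
#>   baseline 0.801 ml/min, score 92.92%
#>   complete occlusion at 708 s; effective recanalization at 5 min
```

The score says post-drug flow averaged 92.9% of the pre-injury baseline;
the artery occluded 708 s into the recording and flow recrossed 50% of
baseline 5 minutes after drug start, staying up for over 30 minutes.

```r
# the seven-group dose-response design, five animals per group
rep <- run_study(dose_response_design(n_per_group = 5, seed_base = 1))
rep
#> <study_report> 35 animals in 7 groups (config 1436080024)
#>   saline                   n=5  score   0.40 +/- 0.01%  recanalized 0/5
#>   1 mg/kg                  n=5  score   0.43 +/- 0.01%  recanalized 0/5
#>   1.75 mg/kg               n=5  score   2.97 +/- 0.60%  recanalized 0/5
#>   2.5 mg/kg                n=5  score  28.36 +/- 2.61%  recanalized 1/5
#>   3.75 mg/kg               n=5  score  90.03 +/- 2.24%  recanalized 5/5
#>   5 mg/kg                  n=5  score  93.39 +/- 0.99%  recanalized 5/5
#>   10 mg/kg                 n=5  score  94.63 +/- 1.84%  recanalized 5/5
#>   anova-tukey p = 1.864e-40
```

Restoration is dose-dependent and saturates near baseline at 5 mg/kg;
ANOVA + Tukey separates treated groups from saline. A total-dose bolus of
the same 5 mg/kg recanalizes faster but reoccludes as the drug (serum
half-life 4.1 min) washes out:

```r
analyze_flow_trace(simulate_flow_trace(5, regimen = regimen_total_bolus(5),
                                       seed = 1))
#> <recanalization_report> sim
#>   baseline 0.801 ml/min, score 34.25%
#>   complete occlusion at 708 s; effective recanalization at 5 min
#>   reocclusion at 72 min
```

In-vitro statistics:

```r
percent_inhibition(8, 16)    # ADP: 8 of 16 ohms -> 50% inhibition
#> [1] 50
fit_half_life(simulate_decay(4.1, noise_cv = 0))
#> <pk_fit> t1/2 = 4.1 min (k_el = 0.1691 /min, R^2 1.0000)
```

## Command line

```sh
thrombolyzer simulate   --out fixtures/ --seed 1     # materialize a study
thrombolyzer analyze-flow --trace m.csv --markers m.json --monitor-min 120
thrombolyzer analyze-agg  --trace a.csv --meta a.json --mode disaggregation
thrombolyzer fit-kd       --titration t.csv --amax-mode plateau
thrombolyzer fit-halflife --decay d.csv
thrombolyzer run-study    --out run1/ --seed 1 --n-per-group 5
thrombolyzer plot         --report-dir run1/ --out figs/
```

(The `thrombolyzer` script installs under `exec/`; it is also callable
in-process as `cli_main(c("fit-kd", ...))`.)

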