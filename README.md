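# cuffbp

Cuffless blood-pressure estimation and benchmarking from ECG and PPG
waveforms, in R.

Continuous, cuff-free blood-pressure monitoring infers systolic, diastolic
and mean arterial pressure (SBP, DBP, MAP = (2·DBP + SBP)/3, all in mmHg)
from signals a wearable can record: an ECG channel for the timing of the
R wave and one or two photoplethysmogram (PPG) channels for the arrival and
shape of the arterial pulse. The open questions in this field are which
features carry the pressure information and which regression model turns
them into clinically acceptable estimates. `cuffbp` packages the whole
benchmarking workflow for those questions, aimed at biomedical-signal
researchers who want a tested, seeded, end-to-end reference implementation.

## What is inside

* **Hemodynamic model** — the closed-form relations motivating the features:
  `BP = k1·log(1/PWV + k2)`;
  `PP = k_pp·(PEP/(PIR·PTT²))·(1 − 0.56/(√2·α))⁻²` with `α` the Womersley
  number; `DBP = a_dbp·ln(drive) + b_dbp`; `SBP = PP + DBP`;
  `MAP = (2·DBP + SBP)/3`
  (`womersley_factor()`, `pulse_pressure()`, `dbp_from_params()`,
  `bp_triple()`, …).
* **Synthetic cohorts** — `synth_config_compromised()` (31 subjects, 126
  ICU-style records, single PPG at 125 Hz) and `synth_config_healthy()`
  (23 subjects, dual PPG at 400 Hz); labels generated through the model
  above, waveforms as stylized ECG/PPG/arterial-pressure records
  (`generate_feature_table()`, `synthesize_cohort()`).
* **Feature extraction** — R-peak and PPG fiducial detection with
  beat-ensemble refinement, automated clean-window selection, and the
  study features: pulse arrival time (PAT), pulse transit time (PTT),
  pulse rate, and eight pulse-wave-morphology features (Tc, Ts, Td, Vp,
  Vs, dVs, Vd, dVd), all averaged over five clean cardiac cycles
  (`extract_record_features()`).
* **Five regression families** — elastic net, boosted regression trees,
  RBF support-vector regression, a 20-unit feed-forward network, and a
  single-time-step LSTM cell trained by Adam — each with its published
  five-trial hyperparameter grid and the lowest-error-SD selection rule
  (`fit_model()`, `hyper_grid()`, `select_hyperparameters()`).
* **Evaluation** — exact leave-one-out and seeded 80:20 / 70:30 holdout
  protocols; bias/SD/95 % CI summaries; IEC 80601-2-30 criterion-1 grading
  (|bias| ≤ 5 mmHg, SD ≤ 8 mmHg); Bland–Altman agreement; the full
  5 methods × 3 feature sets × 3 targets grid (`full_protocol()`).
* **Statistics** — two-way ANOVA on signed errors, two-way mean-centered
  Levene tests on absolute deviations, and Holm-corrected post hoc
  pairwise comparisons (`two_way_anova()`, `levene_two_way()`,
  `posthoc_pairwise()`, `holm_adjust()`).
* **Pipeline** — YAML-configured stages (`pipeline_synth()` →
  `pipeline_extract()` → `pipeline_evaluate()` → `pipeline_compare()` →
  `pipeline_report()`) plus a thin command-line front-end in
  `inst/scripts/bp_pipeline.R`.

The methods vignette (`vignettes/cuffless-bp-methods.Rmd`) documents the
model, the generator's assumptions and limits, the fiducial-detection
numerics and every open design choice.

## Worked example

Generate the ICU-style synthetic cohort, estimate DBP from the PAT feature
set with the published boosted-trees selection, and grade the
leave-one-out errors:

```r
library(cuffbp)

tab <- generate_feature_table(synth_config_compromised(seed = 42))
tab
#> <synth_feature_table> 126 records, 31 subjects, cohort 'compromised'

spec <- benchmark_selected_spec("boosted_trees", "dbp")
spec
#> <bp_model_spec> boosted_trees: splits=120, cycles=500 (seed 1)

errs <- loo_errors(spec, tab$features, "pat", "dbp")
summarize_errors(errs, target = "dbp")
#> # A tibble: 1 x 7
#>   target     n  bias    sd mean_abs_error ci_low ci_high
#>   <chr>  <int> <dbl> <dbl>          <dbl>  <dbl>   <dbl>
#> 1 dbp      126 0.201  3.17           2.63 -0.352   0.755
```

The bias is the mean signed error of the 126 leave-one-out estimates
(+0.20 mmHg: essentially unbiased), the SD (3.17 mmHg) is the spread that
the IEC standard limits to 8 mmHg, and the CI is the normal-quantile 95 %
interval for the bias. Grading against IEC 80601-2-30 criterion 1:

```r
unlist(iec_grade(0.201, 3.17))
#> bias_pass   sd_pass   overall
#>      TRUE      TRUE      TRUE
```

`ci_from_summary()` reproduces published interval bounds from printed
summary statistics, e.g. `ci_from_summary(0.14, 4.51, 126)` gives
`-0.65 0.93`.

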