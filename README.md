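# pegkin

Kinematic features and longitudinal statistics for Purdue Pegboard
accelerometry in Parkinsonism.

## What this package is for

Clinical research on Parkinson's disease (PD) and the atypical
parkinsonian syndromes (PSP, MSA) needs objective, inexpensive markers of
motor decline. The Purdue Pegboard Test (PPT) — pegs placed in 30 s per
hand, or assemblies completed in 60 s — is such a marker, and wearable
triaxial accelerometers recorded during the test expose *why* scores
fall. `pegkin` implements the complete analysis chain for this setting,
for movement-disorder researchers and biostatisticians:

* **Signal conditioning** of accelerometer trials: iterative Hampel spike
  removal, 1–50 Hz 4th-order Butterworth filtering applied forward and
  backward (zero phase, reflective padding), and integer decimation.
* **Kinematic features** per sensor, averaged over the x/y/z axes:

  * SD of acceleration — movement vigor, `sd(a)`; a pure harmonic of
    amplitude `A` has SD `A/√2`;
  * approximate entropy — movement irregularity,
    `ApEn(m, r, N) = Φ_m(r) − Φ_{m+1}(r)`, the classical self-match
    counting statistic with Chebyshev distance, `m = 2`,
    `r = 0.2·SD` (compiled kernel, oracle-tested).
* **Longitudinal statistics**: one-year change scores
  (`visit2 − visit1`), one-way and mixed-design ANCOVAs (Type III sums of
  squares, sum-coded factors, Greenhouse–Geisser correction), post hoc
  families with Benjamini–Hochberg FDR adjustment *within* each declared
  family, and Spearman/Pearson change–change correlations.
* **Prediction**: backward-elimination linear regression of follow-up
  pegboard score on 40 baseline candidates (age, sex, disease duration,
  MOCA, and free-water / corrected-FA values for 18 motor regions and
  tracts), removing the least significant term until all retained terms
  have `p < 0.05`; standardized betas, adjusted R², deterministic
  elimination trace.
* **Synthetic data** for every input — accelerometer trials with
  independently dialable vigor and irregularity, longitudinal cohorts
  with planted group declines and a copula-planted change correlation,
  and predictor matrices with a planted sparse linear model — so the
  entire pipeline is testable without patient data.

## Worked example

```r
library(pegkin)

# 1. simulate a longitudinal multisite cohort (PD / PSP / MSA / HC)
cohort  <- generate_cohort(cohort_design(), seed = 1)
changes <- one_year_change(cohort, tasks = c("dominant", "both"))
subset(change_summary(changes), task == "both")
#>   diagnosis task mean_change sd_change   n
#> 1        PD both  -1.4819725  3.359439 164
#> 2       PSP both  -1.8641207  4.292652  39
#> 3       MSA both  -1.5720065  3.066605  23
#> 4        HC both   0.3244305  3.392525  53
```

The parkinsonian groups lose one to two pegs per year on the both-hands
task while controls do not — the planted longitudinal pattern. The
FDR-corrected post hocs separate each disease group from controls:

```r
posthoc_group_changes(changes, "both")
#>   comparison    estimate          t       df           p       p_adj
#> 1  HC vs MSA  1.89643702  2.3968544 46.07572 0.020649365 0.041298730
#> 2   HC vs PD  1.80640301  3.3779522 87.38005 0.001092364 0.006554182
#> 3  HC vs PSP  2.18855115  2.6353958 70.13108 0.010337041 0.031011124
#> 4  MSA vs PD -0.09003401 -0.1302669 29.91433 0.897227300 0.897227300
#> 5 MSA vs PSP  0.29211413  0.3111550 57.65222 0.756805081 0.897227300
#> 6  PD vs PSP  0.38214814  0.5194131 49.62987 0.605781574 0.897227300
```

Pegboard decline tracks motor-scale worsening (the generator plants a
Spearman correlation of −0.30 on the dominant-hand task):

```r
dis <- subset(changes, diagnosis != "HC" & task == "dominant")
correlate_changes(dis$updrs_change, dis$change, "spearman")[c("estimate", "p")]
#> $estimate
#> [1] -0.2996099
#> $p
#> [1] 4.541783e-06
```

A simulated accelerometry sub-study (20 PD vs 19 HC) recovers the
kinematic group pattern — lower SD of acceleration in PD on the sensors
the task engages, significant after within-task FDR:

```r
feats <- simulate_accel_features(task = "dominant", seed = 2)
sensor_group_tests(feats, "sd_accel", "dominant")[, c("sensor", "t", "p", "p_adj")]
#>   sensor        t            p        p_adj
#> 1    NDH 1.616509 0.1156229402 0.1156229402
#> 2    NDB 4.201259 0.0003761737 0.0009218589
#> 3     DH 4.128707 0.0002199619 0.0009218589
#> 4     DB 3.543293 0.0013336333 0.0016670416
#> 5     HD 3.808899 0.0005531154 0.0009218589
```

Single-trial kinematics and the predictive regression:

```r
prof  <- accel_profile(amplitude = 0.1, irregularity = 0.3,
                       duration = 30, sampling_rate = 2000)
trial <- generate_accel_trial(prof, seed = 3)
extract_sensor_features(trial)
#> <sensor_features> subject S01, sensor DH, task dominant
#>   sd_accel = 0.069374 g, apen = 1.0952

sim <- generate_predictors(predictor_design(), seed = 4)
backward_eliminate(sim$x, sim$y)
#> Backward elimination (alpha = 0.05): 9 of 40 candidates retained
#>               term   beta      t        p
#>             FW_pSN -0.142 -2.020 4.53e-02
#>             FW_PPN  0.179  2.524 1.27e-02
#>        FW_SMATT_M1 -0.250 -3.441 7.62e-04
#>             FW_SCP  0.189  2.661 8.70e-03
#>            FAt_MFG  0.178  2.550 1.19e-02
#>            FAt_STN  0.309  4.409 2.04e-05
#>            FAt_pSN -0.347 -5.072 1.22e-06
#>   FAt_SMATT_preSMA -0.157 -2.151 3.31e-02
#>  FAt_nigrostriatal  0.140  1.980 4.96e-02
#> Adjusted R2 = 0.325, F(9, 141) = 9.041, p = 1.03e-10
```

The end-to-end orchestration (`run_pipeline()` with a YAML-configurable
`pipeline_config()`) runs all of the above from one seed and writes the
report tables, a provenance record, and a run log to an output directory.

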