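# imugait

Can a pair of thigh- and shank-mounted inertial sensors (IMUs) tell a
restricted knee from a restricted ankle, where a pressure-sensitive walkway
cannot? `imugait` is an R package for wearable-sensor gait analysis under
simulated joint impairment. It provides, end to end:

- a **synthetic gait generator** — 50 Hz bilateral thigh/shank sagittal-angle
  waveforms plus walkway footfall records with ground-truth heel-strike (HS)
  and toe-off (TO) times, for cohorts of subjects walking normally, with a
  knee brace, and with an ankle brace, calibrated to published per-condition
  descriptive statistics (e.g. right knee sagittal ROM 55.63° normal vs
  12.81° knee-restricted);
- **event detection** on shank angular velocity: prominent-trough labelling
  around the dominant mid-swing peak (prominence 20 deg/s, minimum distance
  20 samples), cycle construction, and left/right cycle pairing by temporal
  overlap;
- **gait parameters**: 21 IMU parameters per cycle pair and 25 walkway
  parameters per gait cycle, including the symmetry ratios

  ```
  TSR  = (swing_R / stance_R) / (swing_L / stance_L)
  SSR1 = (shank_R / thigh_R) / (shank_L / thigh_L)
  SSR2 = knee_R / knee_L
  ```

- **classification**: recursive feature elimination with subject-grouped
  5-fold cross-validation (RFECV) and linear SVM / random forest / gradient
  boosting back ends, with accuracy, precision, recall, F1 and confusion
  matrices;
- **repeated-measures statistics**: subject-level aggregation, Friedman
  tests (chi-square tail, df = k−1), paired Wilcoxon signed-rank post hocs
  (exact by sign enumeration for n ≤ 12) with Bonferroni correction, and a
  descriptive report.

## Worked example

```r
library(imugait)

cohort <- simulate_cohort(sim_config(n_subjects = 5, n_trials = 3, seed = 1))
feats  <- cohort_parameter_table(cohort, "imu")   # detect events + extract

descriptive_report(feats[, c("subject_id", "condition", "trial_index",
                             "cycle_index", "knee_sagittal_angle_R",
                             "ssr2", "tsr")])
#>               parameter normal_mean normal_sd knee_mean knee_sd ankle_mean ankle_sd friedman_statistic p_value
#> 1 knee_sagittal_angle_R       54.99      2.01     11.62    4.39      35.27    15.49                8.4   0.015
#> 2                  ssr2        0.94      0.04      0.21    0.07       0.70     0.22                8.4   0.015
#> 3                   tsr        1.01      0.04      1.45    0.19       1.40     0.19                8.4   0.015
```

The braced (right) knee's range of motion collapses from ~55° to ~12°, the
knee/knee symmetry ratio SSR2 drops to ~0.2, and the temporal symmetry ratio
rises to ~1.45 under either brace; the Friedman statistic of 8.4 at n = 5
subjects gives p = exp(−8.4/2) = 0.015 across the three conditions.

```r
res <- run_task(feats, "three-class", "imu", classifier_spec("rf"), seed = 1)
res$summary
#>  system        task classifier optimal_n_features accuracy precision recall    f1
#>     imu three-class         rf                 20     0.96      0.97   0.96  0.96
head(res$selection$optimal_features, 3)
#> [1] "ssr2" "knee_sagittal_angle_R" "cadence_L"
res$report$confusion
#>        normal knee ankle
#> normal     56    0     2
#> knee        0   57     1
#> ankle       0    4    56
```

Grouped cross-validated random-forest classification of the three walking
conditions reaches 96% accuracy on this small synthetic cohort, led by the
right knee angle and its symmetry ratio; the few confusions are between the
knee and ankle conditions. Running the same task on the walkway parameters
(`cohort_parameter_table(cohort, "walkway")`) lands markedly lower — the
spatio-temporal parameters do not carry the joint-specific signal.

The full pipeline (simulate → detect → extract → classify → stats, with
per-stage tables and JSON manifests) is available as `run_pipeline()` or
from a shell via the wrapper in `inst/cli/imugait.R`:

```sh
Rscript inst/cli/imugait.R run-all --seed 1 --out runs/demo
```

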