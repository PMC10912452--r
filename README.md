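# handkin

Time-resolved kinematic profiling of fine hand movements from triaxial
accelerometer recordings, for quantifying bradykinesia — the pathological
slowing and decrement of voluntary movement that is a cardinal sign of
Parkinson's disease. Standard clinical practice rates bradykinesia with
ordinal MDS-UPDRS Part III item scores (0–4 per side), a subjective,
time-averaged categorization. `handkin` implements the complementary
quantitative route: detect every individual finger tap or
pronation–supination rotation in a ~10 s accelerometer block, extract
per-event kinematics, condense them into a data-driven *movement-profile
score* per observation, and relate profiles and therapy state (levodopa ×
subthalamic deep-brain stimulation, four ON/OFF combinations) to the
clinical scores with linear mixed-effects models.

Because patient recordings of this kind are not openly available, the
package ships a first-class synthetic generator: accelerometer blocks with
known ground-truth events, and a cohort (subjects × 4 therapy states × 2
movement types with coupled ordinal UPDRS items) whose generation
parameters are recorded so every downstream stage can be tested against a
known truth.

## Method overview

1. **Preprocessing** — zero-phase 3rd-order Butterworth high-pass (1 Hz)
   per axis, vector magnitude `|a(t)| = √(ax² + ay² + az²)`, centered
   50 ms RMS envelope, and jerk (d|a|/dt, m/s³).
2. **Two-stage event detection** — candidate windows where the RMS
   envelope or |jerk| exceed per-block percentile thresholds (90/95 for
   finger tapping, 80/85 for rotations), merged across <50 ms gaps and
   filtered at 30 ms minimum duration; then peak confirmation requiring
   topographic prominence ≥ 2.5·SD(|a|) and ≥ 100 ms peak spacing.
3. **Kinematic features** — per event: duration-normalized acceleration
   magnitude (mean |a| over onset→offset, m/s²), mean |jerk|, duration;
   per block: means and coefficients of variation (100·SD/mean) of
   acceleration, inter-movement interval (peak-to-peak, ms) and jerk, plus
   standardized decrement slopes of acceleration and interval over trial
   number from random-slope mixed models (per-subject conditional modes).
4. **Movement profiles** — z-score the eight block features, reverse-code
   the ones where higher = better (acceleration, jerk, acceleration
   slope), run maximum-likelihood single-factor analysis with iterative
   pruning of weak loadings (|λ| < 0.70; RMSEA/CFI/SRMR and χ² reported
   per model), then score observations on the first principal component of
   the retained set, oriented so lower = better performance.
5. **Clinical models** — single-trial metrics ~ therapy state (4 levels)
   with subject and trial-within-subject random intercepts, Satterthwaite
   F tests and Tukey-adjusted pairwise comparisons; profile scores →
   UPDRS outcomes (total, item 3.4/3.6, right-sided bradykinesia sum =
   items 3.4–3.8) controlling for the symptom laterality index
   (left-sum − right-sum, negative = right-dominant), with Nakagawa
   marginal/conditional R².

Satterthwaite degrees of freedom, mixed-model Tukey contrasts
(studentized-range adjustment on estimated marginal means), Nakagawa R²
and the factor fit indices are implemented in-package (validated against
lmerTest/emmeans and scipy during development); only `lme4`, `Matrix` and
`jsonlite` are required at run time.

## Worked example

```r
library(handkin)

params <- block_sim_params(movement_rate_hz = 4, burst_amplitude = 10,
                           rng_seed = 42)
snr_db(params)
#> [1] 9.8
blk <- simulate_block(params)
events <- detect_events(blk$trace, detection_config("finger_tapping"))
head(as.data.frame(events), 3)
#>   event_index onset_s peak_s offset_s peak_magnitude
#> 1           1   0.110  0.129    0.187       9.452726
#> 2           2   0.361  0.411    0.433      10.134641
#> 3           3   0.628  0.646    0.668       9.375142
match_events(events, blk$truth, tol_ms = 30)[c("sensitivity", "ppv")]
#> $sensitivity 0.975   $ppv 1
```

39 of the 40 simulated taps are recovered (one weak-amplitude tap falls
below the percentile windows at ~10 dB SNR), with no false positives.
Block-level features:

```r
tf <- block_trial_features(blk$trace, events)
block_features(tf, tf$imi_ms[!is.na(tf$imi_ms)])[, 1:6]
#>   accel_mean accel_cv imi_mean imi_cv jerk_mean jerk_cv
#> 1       4.09    20.11   256.08  21.62    427.97   13.11
```

`accel_mean` is the mean event-wise |a| in m/s²; `imi_mean` ≈ 256 ms is
the inter-tap interval for ~4 Hz tapping; CVs are in percent.

Full pipeline on a 20-subject synthetic cohort (4 therapy states × 2
movement types, ~2 minutes):

```r
rep <- run_pipeline(validate_config(list(n_subjects = 20, rng_seed = 1,
                                         out_dir = "handkin_out")))
print(rep)
#> <run_report> seed 1
#>   blocks: 160 simulated, 160 retained; 4524 events featurized
#>   finger_tapping: 80 obs, retained [accel_mean, accel_cv, imi_cv, jerk_mean, jerk_cv], var explained 87.9%
#>   pronation_supination: 80 obs, retained [accel_mean, imi_mean, imi_cv, jerk_mean], var explained 84.1%

rep$stages$clinical$profile_models$ft_on_updrs_total$anova
#>               term      F ndf  ddf        p     df_method
#> 1       ft_profile 329.00   1 69.6 4.43e-28 satterthwaite
#> 2 laterality_index   4.09   1 30.5 5.19e-02 satterthwaite
```

Lower finger-tapping profile scores (better performance) predict lower
synthetic UPDRS totals with a positive coefficient, mean profile scores
order ON/ON best → OFF/OFF worst, and the therapy-state effect on
single-trial tap acceleration is strongly significant with all six Tukey
contrasts separating (the synthetic effect multipliers are deliberately
strong; observed patient effects are subtler).

The command-line interface wraps the same stages:

```sh
Rscript inst/cli/handkin run-all --seed 1 --out handkin_out
Rscript inst/cli/handkin simulate --seed 1 --out cohort_dir
Rscript inst/cli/handkin detect --out cohort_dir
```

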