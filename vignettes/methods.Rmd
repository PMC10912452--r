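---
title: "Quantifying bradykinesia from accelerometer kinematics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bradykinesia from accelerometer kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`handkin` turns a ~10 s triaxial accelerometer recording of repetitive
hand movements into single-trial kinematics, a per-observation
movement-profile score, and mixed-model estimates of how therapy state and
profile relate to clinical bradykinesia ratings. This vignette documents
the model underlying each stage, every tunable parameter that matters, the
synthetic world the tests run in, and the design choices made where the
procedure was genuinely under-determined. No empirical claim is made here
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Signal model and preprocessing

The recorded acceleration is modelled as a train of short movement events
on top of gravity/posture drift and sensor noise. Preprocessing removes
the quasi-static component with a 3rd-order Butterworth high-pass at 1 Hz,
applied forward and backward (`highpass_filter()`). Zero-phase filtering
is a deliberate choice: events are *timed* downstream (±30 ms matching,
100 ms spacing rules), and a causal filter would bias onsets and peaks by
a frequency-dependent group delay. The cost is that the two passes square
the magnitude response: attenuation in dB doubles, and the effective
−3 dB point sits slightly above 1 Hz. A 5 Hz tone passes within 2%, a
0.1 Hz tone is attenuated by far more than 40 dB.

Derived series: the vector magnitude |a(t)| (m/s²); a centered RMS
envelope with truncated edges (default window 50 ms — short enough to
resolve the 100 ms minimum peak spacing, long enough to average one
carrier half-cycle of a tap); and jerk as the central first difference of
|a(t)| scaled by the sampling rate (m/s³), with one-sided differences at
the endpoints. Jerk is differenced on the magnitude, not per axis,
because all detection rules are phrased on the accelerometer vector.

**Noise amplification in jerk.** Differencing white noise of SD σ at
sampling rate fs yields jerk noise of SD ≈ σ·fs/√2 — about 240 m/s³ at
σ = 0.5, fs = 1000 Hz. A movement's jerk amplitude is roughly
(peak acceleration)·2π·(carrier frequency), so brisk 12.5 Hz tap carriers
(~780 m/s³ at 10 m/s²) stand clear of the noise floor while slow
rotation carriers may not. This is why jerk-based thresholds help
tapping detection more than rotation detection at realistic noise, and
why the rotation template (below) has two carrier cycles.

## 2. Two-stage event detection

Stage one (`candidate_windows()`) marks a sample *active* when the RMS
envelope exceeds its per-block percentile threshold **or** |jerk| exceeds
its own (presets: 90th/95th percentile for finger tapping, 80th/85th for
pronation–supination; linear-interpolation percentile definition, R type
7). Maximal active runs become windows; windows separated by less than
50 ms merge; windows shorter than 30 ms are dropped. The OR combination
is the default because taps have high-jerk, low-RMS flanks; AND is
available via `detection_config(combine = "and")`. Activity is *strictly*
above threshold, so a constant block (e.g. all zeros) yields no windows;
for continuous-valued data this is almost surely identical to ≥.

Stage two (`confirm_events()`) finds peaks of the magnitude series with
topographic prominence ≥ 2.5·SD(|a|) over the full block, thins them
greedily (tallest first, earlier peak on exact ties) to enforce ≥ 100 ms
spacing, and keeps each window containing at least one surviving peak as
one movement event (peak = highest confirmed peak inside). The phrase
"2.5 SD above the accelerometer vector magnitude" is ambiguous; it is
implemented as a prominence threshold of 2.5 standard deviations of the
full-block magnitude series, with both the multiplier and the
confirmation series (`confirm_on = "magnitude"` or `"rms"`)
configurable.

**Degenerate inputs.** Every threshold above is relative to the block's
own statistics: percentiles of the RMS/jerk series themselves, and a
prominence cut proportional to SD(|a|). Consequently a pure-noise block
*always* contains supra-threshold structure, and the detector reports
events in it (~30 per 10 s at default settings; the acceptance suite
measures and prints this rate). This is not a bug to be tuned away: any
scale-free detector has it, and the original procedure relied on visual
inspection to reject such blocks. `handkin` deliberately automates no
visual step; the corresponding acceptance assertion (noise-only → 0
events) is left failing, with `flag_clipped()` providing the only
automated artifact screen (absolute clip bound, default 50 m/s²).

## 3. Kinematic features

Per event: `norm_accel_magnitude` — the time integral of |a| over
onset→offset divided by duration, i.e. the mean magnitude over the event
window. "Normalized to movement duration" is read this way because the
stated unit remains m/s²; dividing instead by duration in ms (changing
units) is available as `normalize = "per_ms"`. Also mean |jerk| over the
window and duration in ms. Per block: means and coefficients of variation
(100·SD/mean, sample SD) of acceleration, inter-movement interval
(successive peak-to-peak differences, ms) and jerk.

Decrement slopes (`kinematic_slopes()`): within each therapy-state ×
movement-type group, the z-scored feature is regressed on the z-scored
trial number (1-based event index, not elapsed time) with a random
intercept and slope per subject; the per-subject slope is the fixed slope
plus the subject's conditional (shrunken) deviation. Conditional modes
are the standard per-subject summary when one value per participant is
needed downstream; a per-subject OLS fallback (the correlation between
feature and trial index, which is the standardized slope) is used, and
flagged, when the mixed fit is singular or fails — including the
single-subject case, where the mixed model degenerates to OLS exactly.
Sign conventions: negative acceleration slopes = amplitude decrement;
positive interval slopes = pacing decrement (slowing).

## 4. Movement profiles

The eight block features are z-scored and reverse-coded
(`reverse_code()`) so higher always means worse: acceleration magnitude,
jerk (in this feature vocabulary higher jerk = brisker, smoother
execution) and the acceleration slope are negated; the CVs, the interval
(longer = slower) and the interval slope already point the "worse" way.

A single-factor maximum-likelihood model (`stats::factanal` on the
correlation matrix) is fitted and weak features pruned one at a time —
always the smallest |λ|, ties broken alphabetically, never below three
features. **Stopping rule**: pruning stops when all loadings reach 0.70.
Fit indices — χ² = (n−1)·F_min (Bartlett scaling available), RMSEA with a
90% CI by noncentral-χ² inversion, CFI against the independence baseline,
SRMR over off-diagonal standardized residuals (diagonals are zero on a
correlation matrix) — are computed for every model and the final model is
flagged when it misses the conventional cuts (non-significant χ²,
RMSEA < 0.06, CFI > 0.95, SRMR < 0.08). The criteria do not, by default,
drive further pruning once loadings pass: sequential χ²/RMSEA gating at
df ≤ 2 rejects a *true* single-factor model at its nominal error rate
(~13% for RMSEA < 0.06 at df = 2, n = 300), so a fit-gated loop would
discard well-measured indicators at random. `gate_on_fit = TRUE` restores
strict gating for sensitivity analysis. With three indicators the model
is saturated (df = 0) and χ² = 0, RMSEA = 0, CFI = 1 identically.

Scoring is deliberately a hybrid, mirroring the published procedure: the
ML factor analysis decides *which* features are retained; the score is
the first principal component of the standardized retained features
(`profile_scores()`, `method = "pca"`; Thomson regression scores from the
factor model via `method = "efa"`). The component sign is fixed so the
anchor feature (reverse-coded acceleration magnitude) loads positively,
making lower scores = better performance deterministically — no
run-to-run orientation flips. Variance explained = first eigenvalue / p.
Profiles are computed per subject × therapy-state observation (the
80-row design), not per patient: the clinical models regress outcomes on
profiles across states, which requires within-subject variation.

## 5. Clinical derivations and mixed models

From MDS-UPDRS Part III items: side-wise bradykinesia sums (items
3.4–3.8, range 0–20); the symptom laterality index = left sum − right sum
(negative = right-dominant); the tremor/bradykinesia subtype ratio
(mean of items 3.15–3.18 over the mean of items 3.4–3.8 both sides plus
3.14; ratio > 1.5 ⇒ tremor-dominant, zero numerator ⇒ akinetic-rigid,
zero denominator ⇒ tremor-dominant, both zero ⇒ indeterminate; the
boundary 1.5 itself classifies akinetic-rigid, since only ratios *greater
than* 1.5 are defined as tremor-dominant). Observations rated 4 on the
analysed item are excluded (`exclude_item4_observations()`), as a 4
conventionally means inability to perform the task.

`lme_single_trial()` fits metric ~ therapy_state with random intercepts
for subject and trial-within-subject ("nested random effect" read as the
two variance components), by REML. The F test of the 4-level state factor
uses Satterthwaite denominator degrees of freedom computed in-package:
the covariance of the variance parameters is twice the inverse Hessian of
the REML criterion in (θ·σ, σ) parameterization, contrast variances are
differentiated numerically, and multi-df tests use the eigen-contrast
form. Satterthwaite was chosen because fractional denominator df are the
observable signature of such an approximation in the reported statistics.
The degenerate-fit ladder is fixed and logged: singular nested fit →
drop the trial term; still singular → ordinary least squares (where the
state F test equals the one-way fixed-effects ANOVA exactly — the test
suite asserts this equivalence, and the Tukey table then reproduces the
classical HSD). `tukey_posthoc()` compares all six state pairs on
estimated marginal means with per-contrast Satterthwaite df and
studentized-range-adjusted p values. `lme_profile_on_updrs()` regresses
an outcome on one or two profile scores (plus their interaction when
both are given), controlling for the laterality index, with a subject
random intercept, reporting unstandardized b, Satterthwaite F per term,
and Nakagawa marginal/conditional R² — conditional R² is the
variance-explained statistic reported for the full model, alongside the
marginal value, since the original statistic was unnamed. The laterality
covariate enters per med/stim condition (a per-subject mean is a trivial
aggregation upstream).

## 6. The synthetic world

`simulate_block()` realizes ⌊rate·duration⌋ events. The event template
is a Gaussian-windowed cosine: envelope SD = width/4 (support ≈ ±width/2),
carrier = cycles·1000/width Hz, projected on a fixed unit orientation
vector — smooth, biphasic, and peaked exactly at the annotated time so
the noiseless magnitude peak falls within one sample of ground truth.
Defaults state the emulated world once:

| parameter | default | rationale |
|---|---|---|
| duration | 10 s | one standardized movement block |
| sampling rate | 1000 Hz | typical lab acquisition; anything ≥ 200 Hz resolves the 100 ms spacing |
| tap rate / width / cycles | 4 Hz / 80 ms / 1 | brisk index-to-thumb tapping, one accel–decel pair |
| rotation rate / width / cycles | 2 Hz / 250 ms / 2 | a full pronation–supination cycle is longer and has two movement phases; this yields the high duty cycle that the lower 80/85 percentile preset presupposes |
| burst amplitude | 10 m/s² | ~1 g movement peaks |
| amplitude / interval jitter | CV 0.10, log-normal | positivity; ~10% trial-to-trial variability |
| noise SD | 0.5 m/s² per axis | puts the default block at ≈ 9.8 dB SNR (`snr_db()`), the hardest level the detection benchmark admits |
| drift | 0.2 m/s², < 0.5 Hz | residual posture sway below the filter band |
| tremor | off (4–6 Hz sinusoid available) | optional contaminant only |

Block SNR is defined as mean burst-train signal power across axes over
total white-noise power (3σ²); `noise_sd_for_snr()` inverts it.

`simulate_cohort()` draws a latent severity per subject (standard
normal) and modulates block parameters per therapy state by the
`effect_multipliers()` table, ordered OFF/OFF worst → ON/ON best
(amplitude gains 1.00/1.20/1.25/1.50; interval gains 1.00/0.92/0.90/0.75;
variability gains 1.00/0.80/0.80/0.60; smoothness gains
1.00/1.10/1.10/1.25, realized as proportionally narrower, higher-jerk
bursts). Severity scales amplitude down and interval/variability up on a
log scale. UPDRS items are generated by binning latent = 0.8·severity +
state offset (+1.1/+0.45/+0.35/−0.7) plus shared-per-item noise at fixed
cut points (−0.5, 0.5, 1.5, 2.5) into 0–4; left/right asymmetry enters as
± half the subject's laterality offset. Because the item noise is shared
between sides, a zero laterality offset yields exactly symmetric scores
(laterality index ≡ 0). Tremor items are shifted down (−1.2), matching a
predominantly akinetic-rigid cohort. `updrs3_total` is the sum of the
modelled items (a reduced item set — totals are smaller than full-scale
Part III totals). All realized per-block parameters are returned for use
as test oracles.

**What a green test establishes — and what it does not.** The generator
produces clean burst trains with stationary Gaussian noise, a single
fixed orientation, no voluntary pauses, hesitations, dysmetric partial
movements, sensor dropouts or movement artifacts, and a one-dimensional
severity driving all features. Green tests therefore establish that the
algorithms are implemented correctly and recover planted structure under
the stated model; they do not establish clinical validity, the
real-world detection operating point, or the factor structure of real
patient kinematics (the synthetic single-severity world makes the
single-factor model *true* by construction, which is why its variance
explained, ~85–92%, exceeds values achievable on real data).

## 7. Numerical choices and known limitations

- Butterworth design by bilinear transform with prewarping; filtfilt uses
  odd-extension padding with steady-state initial conditions (validated
  against an independent reference implementation to machine precision at
  matched padding).
- Percentiles: R type 7 throughout; documented because window membership
  at the threshold is discrete.
- Ties in peak retention: exact height ties keep the earlier peak.
- χ² scaling in the factor model: (n−1)·F_min by default; Bartlett
  correction via `chisq_scaling = "bartlett"`. Heywood cases (uniqueness
  at the optimizer bound) are flagged, not fatal.
- RMSEA CI bounds solve P(χ²_{df,λ} ≤ χ²_obs) = 0.95/0.05 by uniroot on
  a bracketed noncentrality, returning 0 at the boundary.
- Satterthwaite Hessians/gradients use central finite differences with
  relative steps 1e−4/1e−5; at boundary (singular) fits the Hessian is
  not positive definite and the code falls back to residual df, flagged
  in `df_method`.
- The trace dialect writes 12 significant digits so numeric round-trips
  agree to better than 1e−9 for accelerometer-scale values.
- Pipeline determinism: one seed governs a run; per-block seeds are drawn
  from the cohort stream; reports contain no timestamps, so identical
  configurations produce byte-identical reports.
- The detection count bound ⌈duration / min peak distance⌉ and the
  monotone decrease of candidate *coverage* with rising thresholds are
  asserted as properties; note the window *count* is not monotone in the
  thresholds (raising a threshold can split a merged window), which is a
  property of the merge rule, not an implementation defect.
- Windows containing two true events closer than the merge gap yield one
  event by construction; at 4 Hz tapping with 10% interval jitter this
  costs ~2% sensitivity at 10 dB SNR.
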