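---
title: "Methods: voice-onset latency as a sleepiness marker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voice-onset latency as a sleepiness marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open. The pipeline studies verbal reaction time (VRT)
— the latency from the start of a voice recording to the first speech sound
— as a passive marker of self-reported sleepiness in older adults completing
remote spoken memory tests.

## 1. Speech onset detection

A recording is represented as full-scale-normalized PCM: integer sample
values are divided by $2^{b-1}$ for bit depth $b$, so amplitudes lie in
$[-1, 1]$ and the most negative 16-bit value maps to exactly $-1$. This is
deliberately *not* per-file peak scaling: peak scaling would force every
recording's maximum to 1.0 and make every file cross any threshold below 1,
destroying the ability to call a file non-speech. Normalization here means
"convert to a common absolute scale", nothing more.

Detection is a single-threshold rule on the left channel. The onset is the
first sample $i$ with $|x_i| > \tau$ (strict; ties at exactly $\tau$ are
not onsets), default $\tau = 0.3$ of full scale, and

$$\mathrm{VRT} = i / f_s$$

with $i$ counted zero-based and $f_s$ the sample rate. A recording with no
exceedance is non-speech. An optional `min_duration_samples` parameter
additionally requires the exceedance to start a run of samples at or above
$\tau$, guarding against single-sample clicks; it defaults to 0 (the first
exceedance wins) because the operative definition of the start time is the
first sample over threshold. Two readings of "VRT" are possible — latency
from recording start to onset, versus a duration from some other start
marker to speech — and the package implements the first (recording start to
first exceedance), which is the one that makes VRT well defined for every
recording.

No prefilter is applied by default. A zero-phase Butterworth high-pass
(`highpass()`) is available for recordings with low-frequency rumble, off by
default because the detection rule is defined on raw amplitudes. MFCCs
(`compute_mfcc()`, Hamming window, triangular mel filterbank, orthonormal
DCT-II) exist purely as audit features for manual validation plots; they
play no role in classification.

**What passing tests show.** Onset detection is verified against a naive
first-exceedance scan on 1,000 random signals and recovers planted
latencies within one sample period. On real speech, the threshold rule's
accuracy depends on recording gain and noise floors — that is exactly what
the manual-validation workflow (Section 3) is for.

## 2. The synthetic cohort generator

No raw study data are publicly available, so every downstream stage is
exercised against a seeded generator (`cohort_config()`,
`generate_cohort()`) whose defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_participants` | 16 | cohort size |
| `n_weeks` | 5 | sessions on days 1, 8, 15, 22 (+ optional week 5) |
| `attempts_per_session` | 33 | recorded attempts per session (~2,200 total) |
| `sleepiness_probs` | .237/.395/.171/.198 (renormalized) | EMA level 1–4 distribution |
| `nonspeech_rate` | 0.061 | attempts whose audio has no speech |
| `invalid_strategy_rate` | 0.14 | session-level self-reported invalid recall strategy |
| `missing_sleepiness_rate` | 0.128 | day-level missing EMA sleepiness |
| `vrt_link` | see below | sleepiness-to-latency coupling |
| `sample_rate` | 16 kHz | synthesized audio rate |

The printed sleepiness percentages sum to 100.1 after rounding; the default
probability vector divides them by 1.001 so they form an exact distribution.

**The latency link.** Latency is lognormal in the sleepiness level:

$$\log L = b_0 + s\,( \text{sleepiness} - 1) + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2).$$

Only marginal VRT summaries are known (median 1.68 s, mean 2.19 s, SD
1.80 s), so $(b_0, s, \sigma) = (0.1062, 0.3148, 0.6365)$ were calibrated
once, numerically, to reproduce exactly those three marginals under the
default sleepiness distribution, and then frozen. The lognormal form
guarantees positivity and the right skew implied by median < mean. Because
the observed coupling direction (longer VRT with greater sleepiness) is
made generative here, tests of the association stages are
parameter-recovery tests, not discoveries.

**Nesting.** Observations are nested in participants, so the generator
supports per-participant random intercepts on both latent sleepiness and
log-latency (`participant_intercept_sd`, `latency_intercept_sd`). Both
default to 0 because the downstream models deliberately ignore nesting; a
nonzero intercept SD lets a user probe how badly that assumption bites.

**Open items decided here.** The EMA caffeine item has no published units;
it is generated as a Poisson count of caffeinated drinks (mean 1.5/day, a
realistic figure for older adults). The cognition scale's response options
are likewise unpublished; it mirrors the mood item as ordinal 1–4. One EMA
record is generated per test day and every attempt that day inherits it;
multiple same-day records are accepted at assembly (last record wins, with
a warning) but are not generated.

**Audio.** `synthesize_recording()` plants low-amplitude uniform noise
(default 0.05 full scale) and, for speech attempts, a 440 Hz tonal burst of
amplitude 0.8 starting exactly at the planted latency; stereo output puts
the signal on the left channel. Non-speech attempts are pure sub-threshold
noise. No attempt is made to synthesize intelligible speech — onset
detection only needs amplitude structure — so synthetic audio cannot
exercise annotator disagreement, reverberation, or breath noise. The
`fig1_cohort()` preset fixes the composition exactly (2,230 attempts; 136
non-speech; 295 invalid-strategy among the speech attempts; 286 missing
sleepiness among the remainder; 1,513 survivors), assigning flag counts by
sampled index sets rather than Bernoulli draws; uniquely in this preset,
sleepiness missingness is applied at attempt level so the composition is
exact.

## 3. Validation workflow and flow accounting

`draw_validation_subsample()` draws `round(fraction * N)` rows without
replacement (default fraction 0.083; a simple random draw by default, with
an optional stratified mode because it is unknowable from counts alone
whether a published subsample was stratified by predicted class).
`build_confusion()` tallies predicted against manual speech labels with
*speech* as the positive class, and `confusion_metrics()` reports

$$\mathrm{PPV} = \frac{TP}{TP+FP},\quad
\mathrm{NPV} = \frac{TN}{TN+FN},\quad
\mathrm{accuracy} = \frac{TP+TN}{N},$$

as exact ratios; a zero denominator yields `NA`, never 0. On the canonical
counts (TP 35, FP 0, FN 14, TN 136) these are 1, 136/150 ≈ 0.9067, and
171/185 ≈ 0.9243 — note the full-precision accuracy is 92.43%, which
presentation rounding at one decimal renders 92.4%.

`apply_corrections()` is the relabeling pass: verified false negatives move
to the speech set, with idempotence enforced (re-applying the same ids is
an error, because they are no longer non-speech). `account_flow()` applies
the exclusion stages in a declarative order (non-speech → invalid strategy
→ missing sleepiness) and records in/removed/out per stage; since each flag
is a property of a row, permuting stages changes per-stage removals but
never the survivor set, and the tests assert exactly that.

Percentages are rounded half-up at presentation only (`round_half_up()`);
stored values are never rounded.

## 4. The association cascade

The cascade runs: random-forest screening → linear model → RESET →
(if RESET rejects) GAM → model comparison.

**Outcome coding.** Sleepiness enters both regressions as numeric 1–4 with
Gaussian error. An ordinal-link model is a defensible alternative, but the
Gaussian reading is the only one under which the linear model and the GAM
share a likelihood scale for AIC comparison, which is the point of the
cascade; an ordinal variant is explicitly out of scope.

**Screening.** A regression random forest ranks candidates by node-purity
importance (total impurity decrease). The default absolute cutoff of 50 is
a convention, not a constant of nature: node-purity totals scale with
sample size, tree count and implementation, so `screen_features()` also
accepts a quantile cutoff, and the small-cohort tests use a proportionally
smaller absolute cutoff. Race is manually excluded by default (a
14/1/1 composition in 16 participants invites imbalance artifacts).

**Linear stage.** OLS with reference coding (female, mood level 1, BZRA
non-use as references; mood categorical because mood levels can act
non-monotonically, cognition numeric). 95% CIs are estimate ± 1.96 SE.
RESET (via `lmtest::resettest`) tests whether squares and cubes of the
fitted values improve the fit — powers {2, 3} being the conventional
default — and a p ≤ 0.05 gates the GAM stage.

**GAM stage.** Thin-plate penalized smooths for the continuous covariates
(VRT, age, education, caffeine, difficulty; basis size k = 10) and
parametric terms for sex, BZRA, mood, cognition, fitted with `mgcv`.
Smoothing is selected by **REML**, not GCV: on linear-truth fixtures GCV
leaves spurious wiggle (effective degrees of freedom up to ~6 where the
truth is a line), while REML reliably shrinks unneeded smooths to
near-linearity; GCV remains available via `method = "GCV.Cp"`. For
low-cardinality covariates such as caffeine counts, k is capped at one
less than the number of unique values (`adapt_k = TRUE`); with
`adapt_k = FALSE` an oversized basis errors with a suggestion to lower k.

**Comparison.** `compare_models()` reports `AIC(linear) − AIC(GAM)`
(positive favors the GAM; both AICs are on the same Gaussian likelihood
scale) and an approximate F-test computed by refitting the linear model in
the penalized framework and comparing residual sums of squares on
effective degrees of freedom. The comparison is approximate because
penalized degrees of freedom are non-integer; when the smooths have shrunk
so far that the effective df difference falls below 0.5, the models are
reported as equivalent (p = 1) rather than feeding a degenerate F
reference — without this guard the test rejects wildly under the null.

## 5. Patient-level cross-validated prediction

The classifier answers a different question from the GAM: can sleepiness
level be predicted for a *new patient*? Folds therefore partition
participants, never observations. `plan_folds()` assigns each patient
(greedily, largest first, in seeded random order within modal sleepiness
class) to the test fold currently holding the fewest patients of that modal
class — a simple stratification that the tests show balances fold-level
sleepiness distributions at least as well as random patient splits. Train
and test patient sets are disjoint by construction and the leakage guard
re-asserts it on every run.

Training folds are balanced by class: classes under the floor (180) are
skipped entirely, classes over the cap (500) are downsampled without
replacement, and a ledger records every decision. Test rows are never
touched; test observations of skipped classes remain and count against
recall — the conservative reading of "skipping" a class. Per-fold feature
selection removes a feature only when its importance is below the cutoff
(20) in *every* fold's training data.

The classifier is a 500-tree random forest on the selected features.
Because 4-level precision/recall/F1 are not uniquely defined, the averaging
mode is explicit: `"macro"` (default), `"weighted"`, or
`"binary-collapse"` (sleepy = level ≥ 2). The binary mode exists because
published fold-level metrics of this kind (e.g. a fold with recall exactly
1.00) are most consistent with a binary reading — though a fold reporting
precision 0.76, recall 1.00 *and* F1 0.90 is internally inconsistent with
any mode, since the harmonic mean of 0.76 and 1.00 is 0.864; no averaging
scheme reproduces such a triple, which is why all modes are provided and
none is asserted against. 95% CIs per fold are bootstrap percentile
intervals over B = 1,000 resamples of the test-set (label, prediction)
pairs. `aggregate_folds()` reports mean ± SD (n−1) across folds.

## 6. Orchestration, seeds, and problem sizes

`run_config()` holds every tunable (0.3, 50, 20, 180, 500, k = 4,
B = 1,000, α = 0.05 live only here, never hard-coded in logic). One global
seed derives one seed per stage as
`(seed mod 21474836) * 100 + stage_index`, keeping derived seeds inside
32-bit range and making any stage independently re-runnable. The full-size
pipeline (2,230 synthesized recordings at 8 kHz, 1,513-row models, 4-fold
RF with B = 1,000) runs in well under a minute; the test suite uses scaled
cohorts (8–16 participants, 5–16 attempts per session) and scaled forests
(100–200 trees) chosen so each property suite completes in seconds while
keeping comfortable statistical margins, with the statistical assertions
(binomial bounds, seed-sweep majorities) computed for those sizes.

## 7. Numerical conventions and degenerate inputs

* Threshold comparisons are strict on absolute amplitude; `threshold`
  outside (0, 1) and empty signals are argument errors.
* Quantiles use linear interpolation (type 7) — IQR endpoints depend on
  this and it is therefore stated; SDs use the n−1 denominator.
* Presentation rounding is half-up; stored values are full precision.
* A constant outcome is a screening error in `screen_features()` (no
  impurity to reduce) but a legal degenerate fit in `fit_linear()`
  (slopes 0, R² reported as 0 rather than NaN).
* Duplicate participant-day EMA records resolve to the last record, with a
  warning; a missing participant record is a schema error.
* WAV quantization: write-then-read error is bounded by $2^{-(b-1)}$;
  classification is invariant to bit depth for the same waveform.

## 8. Known limitations

Synthetic audio is tonal, perfectly gated, and noise-floored well below
threshold, so pipeline-level validation metrics on it are ceiling values;
they demonstrate plumbing, not field performance. The generator's
covariates other than VRT are independent of sleepiness by default, so
multiclass prediction performance on default synthetic cohorts sits only
modestly above chance — which is the honest consequence of a
single-informative-covariate world, and the coupled-versus-uncoupled tests
are designed around that contrast rather than absolute performance.
Participant nesting is ignored by the models (matching the design being
emulated); the generator can produce nested data to study the consequences,
but no mixed-effects stage is provided.
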