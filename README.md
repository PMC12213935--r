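# vrtsleep

Verbal reaction time (VRT) extraction from cognitive-test audio, and
voice-based modeling of self-reported sleepiness.

## The problem

Excessive daytime sleepiness degrades cognition and safety, but it is rarely
measured during the situations where it matters — for example while an older
adult completes a remote, self-administered memory test. When those tests are
spoken, the audio itself carries a free, passive marker: the **verbal
reaction time**, the latency from the start of a recording to the first
speech sound. `vrtsleep` implements a complete, reproducible pipeline for
studying that marker in a cohort of older adults with insomnia and
benzodiazepine-receptor-agonist (BZRA) exposure who completed weekly Verbal
Paired Associates (VPA) tests and daily ecological momentary assessments
(EMA) of sleepiness (ordinal 1–4):

1. **Onset detection** (`detect_onset`, `batch_extract`): the left channel
   of each WAV recording is full-scale normalized to [−1, 1]; speech onset
   is the first sample whose absolute amplitude strictly exceeds a threshold
   (default 0.3), and VRT = onset index / sample rate. Recordings with no
   exceedance are non-speech.
2. **Validation arithmetic** (`draw_validation_subsample`,
   `build_confusion`, `confusion_metrics`, `apply_corrections`,
   `account_flow`): a random subsample is checked against manual labels,
   yielding PPV/NPV/accuracy; verified false negatives are relabeled; an
   exclusion-cascade ledger (non-speech → invalid strategy → missing
   sleepiness) accounts for every recording.
3. **Assembly** (`assemble`, `summarize_cohort`, `sex_difference_tests`):
   onsets, EMA, session plans and demographics are joined into one
   analysis table.
4. **Association cascade** (`run_association`): random-forest node-purity
   screening → linear regression of sleepiness (numeric 1–4) →
   RESET misspecification test → penalized-spline GAM
   (smooths for VRT, age, education, caffeine, difficulty; parametric sex,
   BZRA, mood, cognition) → AIC/ANOVA model comparison.
5. **Prediction** (`plan_folds`, `balance_training`,
   `select_features_per_fold`, `run_skcv`, `aggregate_folds`): patient-level
   stratified k-fold cross-validation (k = 4) with class balancing
   (floor 180 / cap 500), per-fold feature selection (remove only features
   below cutoff 20 in *every* fold), a random-forest classifier of
   sleepiness level, and bootstrap percentile 95% CIs per fold.
6. **Synthetic cohort generator** (`cohort_config`, `generate_cohort`,
   `synthesize_recording`, `fig1_cohort`): because no raw study data exist
   publicly, a seeded generator emulates the study conditions — 16
   participants, weekly sessions on days 1/8/15/22 (optional week 5), EMA
   sleepiness distributed 23.7/39.5/17.1/19.8% over levels 1–4, ~6.1%
   non-speech recordings, 14% invalid-strategy sessions, 12.8% missing
   sleepiness, and a lognormal sleepiness→latency link calibrated so the
   marginal VRT has median 1.68 s and mean 2.19 s. `fig1_cohort()` produces
   the exact flow composition 2,230 → −136 → −295 → −286 → 1,513.

`run_pipeline(run_config(...))` chains all stages end to end from one seed.

## Worked example

```r
library(vrtsleep)

report <- run_pipeline(run_config(seed = 1, preset = "fig1"))
print(report)
```

```
== voice-based sleepiness pipeline report ==
records in: 2230
  - non_speech           removed  136 -> 2094 remain
  - invalid_strategy     removed  295 -> 1799 remain
  - missing_sleepiness   removed  286 -> 1513 remain
analysis-ready: 1513
validation: n = 185, PPV 100, NPV 100
VRT: median 1.67 s, mean 2.18 s (n = 1513)
linear model R^2 = 0.244, RESET p = 5.3e-07
AIC: linear 4046.95 vs GAM 3780.84 (delta 266.12, ANOVA p = 2.8e-51)
SKCV/RF (macro): accuracy 0.26 +/- 0.04, precision 0.30 +/- 0.10, recall 0.27 +/- 0.04, f1 0.26 +/- 0.04
```

Reading the output: the flow ledger accounts for every recording through the
exclusion cascade and ends at the 1,513 analysis-ready attempts. The
validation block reports predictive values of the threshold classifier
against ground-truth labels on a 185-recording subsample (on synthetic audio
the classifier is exact, so both are 100%). The VRT summaries reproduce the
generator's calibrated marginal distribution. The RESET test rejects
linearity — the sleepiness–VRT coupling is lognormal, so the expected
sleepiness is nonlinear in VRT — which triggers the GAM stage; the GAM beats
the linear model by ~250 AIC points. The final block is the patient-level
cross-validated random forest with macro-averaged metrics: with covariates
that are mostly pure noise by construction, only VRT carries signal, so
multiclass performance sits modestly above the 0.25 chance level.

Worked arithmetic on printed validation counts:

```r
confusion_metrics(confusion_matrix(tp = 35, fp = 0, fn = 14, tn = 136))
#> $ppv       1          # 35/35
#> $npv       0.9066667  # 136/150
#> $accuracy  0.9243243  # 171/185
```

## Package layout

- `R/syncohort.R` — synthetic cohort, audio, and the fixed-composition preset
- `R/wav-io.R`, `R/voicesignal.R` — WAV I/O, onset detection, MFCC audit features
- `R/speechvalidation.R` — validation subsample, confusion arithmetic, flow ledger
- `R/assembly.R` — dataset assembly, descriptive summaries, sex-difference tests
- `R/inference.R` — screening, linear model, RESET, GAM, model comparison
- `R/prediction.R` — stratified patient-level CV, balancing, RF, bootstrap CIs
- `R/orchestration.R` — run configuration and the end-to-end pipeline
- `vignettes/voice-sleepiness-pipeline.Rmd` — the methods vignette

## Limitations

Synthetic audio contains tonal bursts, not speech; the validation stage on
synthetic data therefore exercises the workflow, not annotator disagreement
(imperfect-classifier fixtures are covered in the test suite). Sleepiness is
modeled as numeric 1–4 with Gaussian error in both regression stages; an
ordinal-link variant is out of scope. Participant nesting is not modeled in
the association stage (by design the generator's random-intercept SDs
default to 0 to match).
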