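# pcgphase

Heart-sound classification of chronic-heart-failure (CHF) phases. CHF
patients swing between a *decompensated* state (fluid overload, hospital
admission) and a *recompensated* state (optivolemic, discharge). `pcgphase`
implements, in R, a complete phonocardiogram (PCG) analysis pipeline that
decides, from a 15–30 s heart-sound recording alone, which phase a patient
is in — the kind of classifier that could back a home tele-monitoring
stethoscope. It is aimed at biomedical-signal researchers who want a tested,
reproducible reference implementation of every stage, exercised end-to-end
on a synthetic PCG generator with exact ground truth.

## The method

For a recording x(t) sampled at 4 kHz:

1. **Preprocessing** — zero-phase order-4 Butterworth band-pass (25–400 Hz,
   the dominant heart-sound band) and RMS normalization to −20 dBFS
   (RMS = 0.1 full scale).
2. **Segmentation** — a duration-dependent hidden semi-Markov model over the
   cyclic states S1 → systole → S2 → diastole. Emissions are Gaussians over
   four 50 Hz envelope features (homomorphic, Hilbert, wavelet-detail,
   40–60 Hz power); state durations are truncated Gaussians with
   systole/diastole means rescaled to the recording's autocorrelation-based
   heart-rate estimate; decoding is exact semi-Markov Viterbi (C++).
   Segment/recording quality control removes cycles with missing S1/S2
   sounds or drowned in noise, and flags mis-segmented recordings.
3. **Features** — 177 named per-cycle features: BPM and state durations
   with 8 ratios, envelope/RMS/zero-crossing amplitudes, sample entropy,
   skewness, excess kurtosis, 12 PSD bands (25–400 Hz) for systole and
   diastole, 13 MFCCs per state, spectral centroid/bandwidth/contrast/
   flatness/roll-off/slope per state, and Daubechies-4 wavelet log-energies.
   A cyclic sliding window (size 6) yields 354 `m_`/`sd_` features per cycle.
4. **Evaluation** — per training fold, the 40 features with the highest
   mutual information (nearest-neighbour estimator, averaged over 5
   stratified subfolds) feed ten probabilistic classifiers (LR, DT, RF,
   three gradient-boosting variants, SVC, kNN, GNB, SGD). Recordings are
   classified by majority vote of their segments' probabilities at
   threshold 0.5, under subject-wise 10-fold cross-validation stratified by
   acquisition device. Results are reported as mean (SD; t-based 95% CI)
   per metric, with a McNemar p-value matrix and an MI feature ranking, and
   compared against a packaged cardiologist-baseline table.

## Worked example

```r
library(pcgphase)

# a paired cohort: 6 subjects, one decompensated + one recompensated
# recording each, across the two stethoscope profiles
cohort <- generate_cohort(6, c(setup1 = 3, setup2 = 3), seed = 5)

# preprocess -> fit segmenter on the ground-truth annotations -> decode ->
# QC -> extract and window the feature catalogue
pl <- run_pipeline(cohort)

# subject-wise cross-validated evaluation of two of the classifiers
rep <- cross_validate(pl$features, classifiers = c("LR", "GNB"),
                      n_folds = 3, seed = 2, qc = pl$qc)
print(rep)
#> <pcg_cv_report> 3-fold subject-wise cross-validation
#>   LR    acc 1.00 (0.00; 1.00-1.00)  f1 1.00 (0.00; 1.00-1.00)  auc 1.00 (0.00; 1.00-1.00)
#>   GNB   acc 1.00 (0.00; 1.00-1.00)  f1 1.00 (0.00; 1.00-1.00)  auc 1.00 (0.00; 1.00-1.00)

head(rep$mi_ranking, 3)
#>                 feature        mi
#> 1             m_Dur_Dia 0.6921645
#> 2  m_MeanEnv_Ratio_S1RR 0.6921645
#> 3 m_MeanEnv_Ratio_DiaRR 0.6921645
```

Both classifiers separate the phases perfectly here: the generator's default
class effects (faster pulse, shorter diastole, S3 gallop, diastolic
140–300 Hz content when decompensated) are deliberately strong, and the MI
ranking surfaces exactly those diastolic-duration and envelope features.
Accuracy 1.00 means every one of the 12 recordings was voted into its true
phase; `mi` is the average mutual information (nats) between a windowed
feature and the phase label, capped near ln 2 ≈ 0.693 for a balanced binary
outcome. With `null_phase_effects()` (no class differences) the same
pipeline drops to chance.

The cardiologist baseline packaged with the repository:

```r
eb <- expert_baseline()
round(eb$per_expert, 2)
#> expert1 expert2 expert3
#>    0.58    0.67    0.25
eb$overall
#> [1] 0.5
```

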