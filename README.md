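# vfoct

Segmentation-free estimation of visual-field sensitivity from volumetric
macular OCT scans.

## What this is for

Glaucoma management needs the visual field, but automated perimetry
(Humphrey Field Analyzer, HFA) is slow, subjective and noisy, whereas OCT
images the retinal structure that mediates the loss objectively in
seconds. `vfoct` is an R implementation of the full analysis pipeline for
*learning* the structure–function mapping directly from raw 3D OCT
volumes — no layer segmentation, no diagnostic labels — aimed at
researchers who want to study, extend or stress-test that design. It
covers:

* **Grid geometry** (`buildGrid`, `normalizeLaterality`,
  `verticalFlipPermutation`, `trim30to24`): the 24-2 / 30-2 / 10-2 test
  point sets in the OD frame, left-eye mirroring, vertical-flip index
  maps, 30-2→24-2 trimming.
* **Quality control** (`reliabilityFilter`, `ssiFilter`,
  `eyelidArtifactDetect`, `andersonPatellaEligible`): reliability indices
  at the inclusive 33% cut, OCT signal strength ≥ 7, the automatic
  upper-eyelid-artifact rule on superior-row nasal means (strict 6/6/8 dB
  differences), and Anderson–Patella glaucoma eligibility with a
  connected-cluster rule.
* **Label construction** (`pointwiseRegressionLabel`,
  `validityPeriodCheck`, `assemblePairedSample`): per-point least-squares
  regression over the longitudinal series with positive slopes clamped to
  zero (label = series mean), evaluation at the OCT date, clamping to
  [0, 33] dB (points) and [−33, 0] dB (MD), the 6-months-per-test
  validity period, and assembly of the masked 122-value target
  `[52 × 24-2, MD, 68 × 10-2, MD]`.
* **Synthetic data** (`genConfig`, `makeDataset`): a seeded generator of
  layered OCT-like volumes whose local thinning is coupled to field
  sensitivity through the vertical retina/field inversion, longitudinal
  series with non-positive slopes and test-retest noise, injectable
  eyelid artifacts.
* **Training** (`trainConfig`, `patientWiseFolds`, `trainFold`,
  `predictVF`): a compact 3D-CNN regressor (conv/batch-norm/ReLU blocks,
  global average pooling, 30% dropout, one linear map to 122 outputs)
  written in RcppArmadillo, trained with Adam (batch 4), a
  6e−4 → 1e−3 → 6e−4 learning-rate schedule over 3+5 epochs, masked MSE,
  patient-wise 10-fold 8:1:1 cross-validation, vertical-flip augmentation
  and flip-averaged inference.
* **Evaluation** (`pairwiseRMSE`, `pairwiseMAE`, `correlations`,
  `blandAltman`, `severityStrata`, `pointwiseMAEMap`, `compareGroups`,
  `severityErrorRegression`): per-pair-then-average error statistics,
  pooled Pearson/Spearman, Bland–Altman bias and 95% limits of agreement
  with proportional-bias correlation, severity strata, per-point error
  maps, and Bonferroni-corrected Mann–Whitney comparisons (exact
  enumeration for small groups).
* **Orchestration** (`runExperiment`): one call runs
  generate → QC → label → train → evaluate → compare for the
  curated-versus-comprehensive training contrast on synthetic data.

The methods vignette (`vignettes/methods.Rmd`) explains the model, the
conventions and every design decision in detail.

## Worked example

Build a longitudinal 24-2 series, check reliability, and construct the
masked label vector at an OCT date:

```r
library(vfoct)

g24 <- buildGrid("24-2")
g24
#> VFGrid pattern 24-2: 54 points (2 blind spot), 8 rows

d0 <- as.Date("2020-01-01")
exams <- lapply(0:3, function(k)
  VFExam("P1", "P1_E1", "OD", d0 + 180 * k, "24-2",
         thresholds = pmax(30 - 2 * k * 180 / 365.25, 0) + numeric(54),
         md = -3 - k, fpRate = 0.05, fnRate = 0.1, flRate = 0.02))
s24 <- VFSeries(exams)
s24
#> VFSeries P1_E1 [24-2]: 4 exams (2020-01-01 .. 2021-06-24)

reliabilityFilter(s24@exams[[1]])
#> QCDecision: pass (ok)
#>    fp = 0.05, fn = 0.1, fl = 0.02

pointwiseRegressionLabel(s24, 1, d0 + 700)$value
#> [1] 26.16701
```

The series loses 2 dB/year, so the regression line read 700 days after
baseline gives 30 − 2·700/365.25 ≈ 26.17 dB — the label the network is
trained against, in place of any single noisy exam. Pairing with a 10-2
series yields the training unit:

```r
s10 <- VFSeries(lapply(0:3, function(k)
  VFExam("P1", "P1_E1", "OD", d0 + 180 * k, "10-2",
         thresholds = rep(31 - k, 68), md = -2 - k,
         fpRate = 0.05, fnRate = 0.1, flRate = 0.02)))
assemblePairedSample(s24, s10, octDate = d0 + 700, volumeRef = "V0001",
                     patientId = "P1", eyeId = "P1_E1")
#> PairedSample P1 / P1_E1 @ 2021-12-01: 122/122 labelled (24-2: regressed, 10-2: regressed)
```

All 122 outputs are labelled here; a missing or stale block would instead
be masked (53 or 69 entries) and excluded from loss and metrics. A full
synthetic train/evaluate cycle is one call:

```r
report <- runExperiment(pipelineConfig(gen = genConfig(nPatients = 40, seed = 1)))
```

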