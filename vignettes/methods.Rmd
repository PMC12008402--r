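---
title: "Estimating visual-field sensitivity from OCT volumes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating visual-field sensitivity from OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Standard automated perimetry (the Humphrey Field Analyzer, HFA) measures
differential light sensitivity in decibels at a fixed set of test points:
54 points on the 24-2 pattern (52 after excluding the two physiologic
blind-spot points at 15 degrees temporal), 68 on the central 10-2 pattern,
and 76 on the 30-2. Perimetry is slow and noisy because it depends on
patient responses. Optical coherence tomography (OCT), in contrast,
produces an objective 3D image of the retina in seconds, and glaucomatous
sensitivity loss is mediated by thinning of the retinal nerve fibre layer.
`vfoct` implements a complete, segmentation-free pipeline that learns the
mapping from a raw macular OCT volume to the 122-value visual-field vector

\[ y = (t^{24\text{-}2}_1,\dots,t^{24\text{-}2}_{52},\ \mathrm{MD}_{24\text{-}2},\
 t^{10\text{-}2}_1,\dots,t^{10\text{-}2}_{68},\ \mathrm{MD}_{10\text{-}2}) \]

together with the quality control, label construction and agreement
analysis that surround such a model. Because the clinical datasets this
kind of study uses are private, the package ships a seeded synthetic
generator with the same statistical structure, and every stage is
exercised end-to-end on it.

## Grid geometry and laterality

All geometry lives in the right-eye (OD) frame: x > 0 temporal, y > 0
superior, degrees. The 24-2 and 30-2 sets are generated from their lattice
definition (odd multiples of 3 degrees within the pattern's eccentricity
bound; the 24-2 keeps its nasal extension at (-27, +-3)); the 10-2 chart
is transcribed literally, since no closed form is canonical for it, and is
validated by its count (68) and mirror symmetries.

Two permutations matter downstream. The *vertical flip* maps each point to
(x, -y); every supported pattern is symmetric under it, it is an
involution, and the blind-spot pair maps onto itself. It is the index map
that must accompany any vertical flip of the volume. The *laterality map*
converts between the OD-frame order and the left-eye (OS) native chart
order. Note the 24-2/30-2 charts are *not* symmetric under x to -x (the
nasal extension has no mirror partner; rows at y = +-3 have nine points),
so the map is defined between the OD chart and the mirrored, re-sorted OS
chart, which is a well-defined involution. Left-eye exams are re-indexed
into the OD frame once at ingest, and left-eye volumes un-mirrored along
the horizontal en-face axis; this "horizontal flip" is deterministic
preprocessing, never random augmentation.

## Quality control

Four filters, with the conventional cut points as defaults:

* **Reliability**: an exam fails when any of the false-positive,
  false-negative or fixation-loss rates is at or above 33% (the bound is
  inclusive: 0.33 fails, 0.3299 passes).
* **Scan quality**: volumes with a signal strength index (SSI) below 7
  fail; 7 passes.
* **Upper-eyelid artifact** (24-2, OD frame): for the four superior rows
  (y = +21, +15, +9, +3) take the mean of each row's three most nasal
  points, m1..m4 superior to inferior, and form d_k = m_{k+1} - m_k so a
  ptotic lid that depresses the upper rows yields positive differences.
  The exam is flagged when d1 > 6, d2 > 6 and d3 > 8 dB, all three,
  strictly. The published description of this rule is ambiguous about the
  subtraction direction and the AND/OR combination; we chose
  lower-minus-upper (so the thresholds are exceeded in the artifact
  direction) with AND, and both are exposed in `qcConfig()`. The rule is
  invariant to adding a constant to the field.
* **Glaucoma eligibility** (Anderson–Patella): eligible when a connected
  cluster of at least three points has pattern-deviation probability
  stricter than 5% with at least one stricter than 1%, or the PSD
  probability is stricter than 5%, or the glaucoma hemifield test is
  outside normal limits. Contiguity is 8-neighbourhood on the lattice
  (|dx| <= 6 and |dy| <= 6 degrees) and clusters may not cross the
  horizontal meridian — the standard perimetric reading convention; the
  criterion itself does not specify one.

## Label construction at the OCT date

Perimetry is variable test-to-test, so a single exam is a poor label. For
each test point with two or more recorded values, the label is the
ordinary least-squares line of threshold on time, read at the OCT date.
Glaucomatous loss is irreversible, so a *positive* fitted slope is treated
as a learning effect and set to zero; the least-squares refit under the
zero-slope constraint is simply the series mean, which is what we use
(keeping the unconstrained intercept instead would not be least-squares
optimal). With exactly one exam, the value is used directly iff the OCT
lies within 6 months of it. Point labels are clamped to [0, 33] dB and MD
labels to [-33, 0] dB; MD is regressed as its own series rather than
recomputed from the fitted points, since the index is regressed and
clamped separately from the points.

Extrapolating a line far beyond its support is unsafe, so a pair is
dropped when the gap between the OCT and the series exceeds the *validity
period* of 6 months x n for a series of n tests. "The exam the gap is
measured from" is ambiguous in the usual phrasing (most recent overall vs
nearest to the OCT); we measure from the exam nearest to the OCT date,
switchable via `labelConfig(referenceExam = "latest")`.

The assembled target is the fixed-order 122-vector above with a parallel
\{0, 1\} mask (1 = absent). A block whose series is missing or stale is
wholly masked (53 or 69 entries); masked entries carry an inert sentinel
of 0, and a perturbation test verifies that no masked value can influence
any loss or metric. Every OCT of an eye yields its own paired sample.
Time is converted to years through 365.25 days and months through
365.25/12 days; the choice is numerically irrelevant but fixed for
reproducibility.

## The synthetic cohort

`genConfig()` defaults define the study conditions used throughout the
tests and the acceptance script; they were chosen once, as plausible for a
glaucoma clinic population, and are not tuned:

* one study eye per patient; half the eyes are left eyes;
* an en-face layer-thickness field (nominal 100 units) with arcuate wedge
  defects in 60% of eyes, depth ~ N(12, 4) dB, one or two wedges in the
  superior and/or inferior retina;
* per-point sensitivity = clamp(33 - gain x local thickness deficit,
  0, 33) dB with gain 1 dB per unit, the deficit being read at the
  *vertically inverted* retinal locus of each field point — the retina is
  upside-down relative to the field, which is why volume flips must be
  paired with label permutations;
* per-point progression slopes truncated-normal N(-0.5, 0.5) dB/year,
  never positive; five exams per eye at 180-day intervals; test-retest
  noise 1 dB; 5% of exams unreliable; 5% of volumes below SSI 7;
* volumes render the thickness field as the axial extent of a bright
  band (plus deeper constant bands and speckle-like noise); left-eye
  volumes are mirrored as a device would;
* optional eyelid-artifact injection depresses the four superior rows by
  cumulative steps of two-thirds of the depth parameter (at the default
  15 dB: 30/20/10/0 dB), which exceeds the 6/6/8 rule by a wide margin.

What the generator does *not* emulate: realistic OCT speckle physics,
nerve-fibre trajectory anatomy (so the spatial error patterns real models
show near the disc will not reproduce), floor-effect censoring beyond the
simple clamp, and age-normative variation (MD is surrogated by the
unweighted mean deviation from the 33 dB baseline, `simplifiedMD()`).
Passing tests therefore demonstrate that the machinery is correct and can
recover a known structure-function coupling — not that the clinical
accuracy of any published model is reproduced.

## Model and training

The regressor is a compact volumetric CNN: four blocks of (3x3x3
convolution, stride 2, batch normalisation, ReLU), global average pooling,
30% dropout, and a single linear map to the 122 outputs — no hidden layer
between the dropout and the output. Batch normalisation (not instance or
layer normalisation) matters here: the pooled features must retain
*between-sample* severity differences, which per-sample normalisation
destroys. Running BN statistics (momentum 0.1) serve inference. The
default width (8, 16, 32, 64 channels, about 93k parameters at 64x64x32
input) trains in well under a minute per fold on one CPU; an
EfficientNet3D-b0-scale channel plan is configurable but intended for GPU
scale and is not exercised by the tests.

Training follows the fixed recipe: Adam, mini-batch 4, masked MSE (the
squared residuals are multiplied by (1 - mask) and normalised by the
number of unmasked entries in the batch), and a learning rate raised
linearly from 6e-4 to 1e-3 over epochs 1..3 then lowered back to 6e-4
over epochs 3..8. Training runs the eight scheduled epochs and the epoch
with the lowest validation masked loss supplies the final weights.
Targets are z-scored per output position with statistics from the
unmasked *training* entries only (sd floored at 1e-6); masked positions
become 0 after scaling.

Cross-validation is patient-wise: patients are shuffled once by seed into
10 parts; fold i tests on part i, validates on part i+1, trains on the
rest (8:1:1), so no patient ever straddles sets. Augmentation flips the
volume along the superior-inferior en-face axis with probability 1/2 and
permutes labels and mask by the grid's vertical involution (MD entries
fixed). The phrase "flipping applied across all data phases" admits two
readings (an always-on deterministic flip, or flip availability); we use
random flips in training plus deterministic two-view averaging at
inference — prediction is the mean of f(v) and the un-permuted
f(flip(v)) — both exposed in the configuration. All randomness (shuffles,
initialisation, dropout, flips) flows from the single `seed` in
`trainConfig()`; two runs with one seed are bit-identical.

## Evaluation

Following the summary-table convention, RMSE and MAE are computed *per
pair* over that pair's unmasked entries and then averaged across pairs
(the "+-" values are across-pair standard deviations); this differs from
pooled RMSE and the package deliberately applies the same convention to
MAE for internal consistency. Correlations pool all unmasked
(prediction, label) pairs — a per-point averaging variant is available via
`pointwiseMAEMap()` but pooled is the default reading. Bland–Altman
analysis reports the mean difference (estimated minus actual), the 95%
limits of agreement (bias +- 1.96 sd), and the proportional-bias
correlation between pair means and differences. Severity strata follow
mild (MD > -6), moderate (-12 < MD <= -6, both bounds as written) and
severe (MD <= -12). Group comparisons use the two-sided Mann–Whitney U
test — exact enumeration of the permutation null when the smaller group
has at most 8 observations, the tie-corrected normal approximation
otherwise — with Bonferroni correction (default m = 6, the six headline
comparisons) capped at 1. The severity-versus-error trend is a degree-2
least-squares fit of absolute error on actual value plus a Spearman
coefficient.

## The curated-versus-comprehensive experiment

`runExperiment()` reproduces, structurally, the contrast between training
on a curated glaucoma cohort and training on everything that passes
automatic quality control: from one synthetic population it builds a
*comprehensive* training set (all QC-passing samples, eyelid-rule
filtered) and a *curated* subset (eyes meeting the Anderson–Patella
criterion), trains both under identical folds and seeds, evaluates both
on the curated-eligible test subset only, and compares per-pair errors.
No claim is made that synthetic results mirror any published effect size;
the pipeline demonstrates the design, not the clinical magnitudes.

## Problem sizes and numerical choices

The tests and the acceptance script run the full pipeline at 64x64x32
voxels with 150 patients, one fold and the eight scheduled epochs —
about 150 MB of volumes and under a minute of training — which is ample
to recover the strong synthetic coupling (held-out pooled Pearson r
typically 0.55–0.70 against a test-retest noise floor of 1 dB on labels
whose regression already averages much of it out). Degenerate inputs are
handled explicitly: constant volumes min-max-normalise to all zeros;
constant target columns take the sd floor; series with all exams on one
date fall back to the mean; all-masked batches, pairs or positions raise
errors or are excluded with a warning rather than silently producing
NaN. Batch-norm variance uses the population convention with eps 1e-5;
ties in rank-based statistics use average ranks.

## Known limitations

The eyelid rule cannot distinguish a true superior arcuate defect from a
lid artifact — on real data it would discard some genuine glaucomatous
fields, and the synthetic false-positive test only bounds the error on
artifact-free eyes. The surrogate MD is unweighted and normative-free.
The 8-neighbourhood cluster convention is one of several defensible
readings of the eligibility criterion. And the compact CNN is a desk-scale
stand-in for the full-scale volumetric architectures used on clinical
datasets; its numbers say nothing about clinical performance.
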