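---
title: "Methods: copy-number subtype classification with region features and a boosted-tree cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number subtype classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cncascade` assigns breast-cancer samples to the ten Integrative Cluster
(IntClust) subtypes from copy-number data alone. This vignette is the
package's account of the method: the model and its assumptions, the
parameters that matter, what the synthetic generator does and does not
emulate, the numerical choices, and the known limitations.

## The model

A sample is a copy-number profile: an ordered vector of log-ratio values on
a probe grid over chromosomes 1–22 and X (Y and mitochondrial loci are
dropped; they carry no signal for this task). The pipeline is unit-agnostic
— log2 ratios or absolute copy number both work — but units must not be
mixed within a cohort; the package does not police this.

**Region derivation.** The per-class average profile (arithmetic mean per
locus over the class's samples, ignoring missing values; the median is
available as an option) is denoised with a penalized piecewise-constant fit.
For one chromosome the fit minimises

$$\sum_{\text{segments}} \mathrm{SSE} + \gamma \cdot (\#\text{segments} - 1),$$

over all partitions into contiguous segments of at least `kmin` probes.
`pcf_segment()` solves this *exactly* with Bellman dynamic programming in
O(n²) time using O(1) prefix-sum cost queries — exactness is what makes the
enumeration oracle in the test suite possible. Segmentation runs per
chromosome, so a breakpoint is forced at every chromosome boundary and no
region ever spans two chromosomes. The union of all classes' breakpoints,
deduplicated per chromosome, cuts the observed probe span into abutting
regions; per-region mean copy number is the feature vector.

**Scaling.** Every cohort — training included — is z-scored per region
(center = mean, spread = sd over the cohort's non-missing values). This is
the simplest choice consistent with its purpose: a platform or cellularity
effect that acts as a cohort-wide affine map `a·x + b` (a > 0) is removed
exactly, which is the precise sense in which the classifier is
platform-agnostic. Zero-spread regions are flagged degenerate and given
spread 1. Scaling an external cohort uses *its own* parameters, never the
training cohort's.

**Outlier filtering.** Within each class of the training cohort, the local
outlier factor (Euclidean metric, classical k-NN formulation) is computed on
the scaled region features — the model's own space — and samples scoring
above a threshold are removed. Classes with at most `k + 1` members are
skipped. Missing features are median-imputed per region within the class for
the distance computation only.

**The cascade.** Four subtype pairs have near-identical copy-number
profiles: 1/5, 3/8, 4/7 and 9/10. The cascade first trains a six-class
gradient-boosted tree model (softmax, multiclass log-loss) on the merged
labels, then one binary model per pair on only that pair's samples
(lower-numbered class encoded 0, higher 1). At prediction time the six-class
argmax either is a singleton (2, 6) and becomes the final label, or names a
pair whose binary model decides at a 0.5 threshold. The boosted-tree backend
is xgboost; missing feature values route natively through the trees, so
prediction never requires imputation.

**Model selection.** Hyperparameters are tuned by random search over
stratified k-fold cross-validation: per class, samples are shuffled and
dealt round-robin into k folds (every sample in exactly one fold, per-class
fold sizes within one of each other); each sampled configuration is trained
on k−1 folds and scored on the held-out fold, and the configuration with
the lowest mean objective wins — multiclass log-loss for multiclass models,
root-mean-square error against the 0/1 label for binary models. The RMSE is
the *selection* metric; the binary training objective is logistic (both are
recorded in the bundle metadata). Search, folds and model fits are all
seeded and single-threaded, so results are bit-reproducible.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `gamma` | 40 | penalty per breakpoint, in units of the estimated probe-noise variance (below) |
| `kmin` | 5 probes | minimum segment length |
| LOF `k` | 20 | neighbour count |
| LOF `threshold` | 1.5 | removal score; scores near 1 are inliers |
| folds | 5 | stratified CV folds |
| `n_trials` | 50 | random-search draws |
| search space | depth 2–10, eta 0.01–0.3 (log-uniform), 50–500 rounds, row/column subsample 0.5–1, L2 0–5 | conventional boosted-tree bounds |
| scaling floor | 3 samples | minimum cohort size for scaling |

**Penalty normalisation.** A raw `gamma` is only meaningful on one noise
scale. `segment_profile()` therefore estimates the probe noise sd robustly
from successive differences (median |Δ| / (√2 · Φ⁻¹(3/4)) — level changes
are rare among adjacent probe pairs, so this is insensitive to the
aberrations themselves) and uses `gamma · σ̂²` as the effective penalty.
This follows common practice in array-CN piecewise-constant fitting and
makes `gamma = 40` transfer across amplitudes; `normalize = FALSE` exposes
the raw objective. In the noise-free limit σ̂ = 0 the effective penalty is
0 and the tie rule (below) returns the fewest segments with zero error,
i.e. exactly the true level changes.

LOF `k` and the threshold are not identifiable from first principles; 20
neighbours is large enough to be stable inside classes of tens-to-hundreds
of samples, and 1.5 is a conventional cut for "clearly denser than its
neighbourhood is not". The number of samples such a filter removes is a
property of the cohort, not of the method.

## The synthetic generator

`make_archetypes()` + `simulate_cohort()` generate cohorts with the
statistical geometry the cascade design targets, standing in for real
breast-cancer cohorts in all tests:

- ten piecewise-constant archetypes on a probe grid (default 2,000 probes
  allocated to chromosomes by physical length — desk-scale; array platforms
  have 10–100× more probes, which only sharpens region means);
- six backbone archetypes (one per merged class), each with
  `segments_per_class = 6` random aberrant segments of amplitude
  `amp_effect = 1` (±, with mild level noise) — the scale of a strong gain or
  loss in log-ratio units;
- each of the four pairs shares a backbone and differs only in
  `pair_segments = 2` discriminative segments of effect `pair_delta = 0.5`
  — the near-identical-pair structure that motivates merging;
- per-probe Gaussian noise `noise_sd = 0.25`, so the pair effect is 2
  standard deviations per probe (and much more after averaging over a
  region);
- platform effects as cohort-wide attenuation `a` and offset `b`, plus a
  thinned, position-jittered probe grid for the second platform of
  `simulate_two_platform_pair()` (default a = 1.6: the "stronger-signal"
  platform), emulating train-on-arrays / test-on-another-assay;
- uneven class proportions resembling breast-cancer cohorts (largest ≈ 16%,
  smallest ≈ 5%);
- optional uniformly-random missing values.

All randomness flows through one seed; identical seeds give identical
cohorts byte for byte.

What the generator does **not** emulate: real IntClust driver loci and their
genomic positions, heavy-tailed or wave-artefact noise, segment-length and
GC biases, correlated missingness, label noise in the training annotations.
Passing tests therefore demonstrate that the pipeline recovers the structure
it assumes — planted breakpoints, affine platform differences, confusable
pairs — not that it reproduces published accuracies on real cohorts, which
additionally depend on the original data and an unstated segmentation
parameterisation.

## Numerical choices

- **Tie rule.** Equal-cost segmentations (within 1e-9 relative tolerance —
  prefix-sum and two-pass SSE differ in the last ulps, and the tolerance
  also absorbs exact ties in noise-free signals) resolve to fewer segments,
  then to the earlier last breakpoint, recursively. Deterministic, and
  shared by the enumeration oracle in the tests.
- **Breakpoint position.** Breakpoints live *between* probes; the cut is
  placed at the floor of the midpoint of the flanking probe positions, so
  regions are grid-independent and a different platform's probes land
  unambiguously in regions.
- **Boundary ownership.** A locus belongs to the segment/region whose
  1-based inclusive span contains it; abutting intervals cannot both
  contain it. BED export converts to 0-based half-open and back losslessly.
- **Missing values** are first-class: probes missing in all of a class's
  samples leave the class-average locus missing; a region with no
  non-missing probe for a sample yields a missing feature; missing features
  stay missing through scaling and route natively at prediction.
- **Degenerate cases.** All-missing chromosomes are skipped with a warning;
  signals shorter than `kmin` return one segment with a warning; zero-spread
  regions scale with spread 1; confusion-matrix rates with zero denominators
  are reported as undefined (`NA`) and excluded from macro averages with a
  count, never silently coerced to 0; a degenerate MCC denominator returns 0
  with a warning.
- **Binary threshold ties** (probability exactly 0.5) go to the
  higher-numbered class of the pair — arbitrary but documented.
- **Composed probabilities.** The 10-class probability vector distributes
  each merged probability over its pair by (1−p, p) from the binary model
  and copies singleton probabilities, then renormalises (the backend's
  float32 softmax sums to 1 only within ~1e-7). This composition is an
  artefact convenience: the final label is the cascade's decision path,
  which coincides with the composed argmax whenever the six-class and
  binary models are reasonably confident — asserted empirically on
  separable synthetic data, not guaranteed for arbitrarily uncertain
  predictions.

## Design decisions on open points

- Every cohort is scaled, including training. Scaling only external cohorts
  would let the training cohort's raw scale leak into the model while
  external cohorts see a different map.
- LOF runs on scaled region features (the model's own space), not on raw
  probes.
- The six-class objective is softmax log-loss (not one-vs-rest).
- The pair-degenerate control in the acceptance material uses a *balanced*
  class mixture, so that the chance level of within-pair assignment is
  exactly 0.5; with uneven pairs a signal-free binary model converges to
  the majority side and "chance" would be the majority share instead.
- Labels are plain integers 1–10; ER-status sublabels of some published
  taxonomies are out of scope.

## Problem sizes in the test material

The test suite and `scripts/acceptance.R` run the full pipeline on
two-platform pairs of 1,000 training / 500 test samples on the 2,000-probe
grid (five seeds for the recovery and non-inferiority checks; 800 test
samples for the pair-degenerate control so the chance band is tight), and
exhaustive-enumeration / naive-reference oracles at small n (signals of
length ≤ 12 for segmentation, ≤ 200 points for LOF, 1,000 random confusion
matrices for the metrics). These sizes were chosen so the pipeline's
properties are measurable in minutes on one CPU.

## Known limitations

- **Cohort-composition sensitivity of z-scoring.** Per-region means and sds
  depend on the cohort's class mixture, so the scaled value of the *same*
  sample differs between cohorts with different compositions or sizes. With
  hundreds of samples per cohort this shift is small; for small cohorts it
  moves class clusters relative to the trees' learned thresholds and
  degrades transfer — the method is unreliable for classifying a single or
  a few samples, and a scaling floor of 3 samples is enforced mechanically
  while realistic use needs far more.
- Regions inherit whatever the class-average segmentation finds; no
  telomere/centromere masking or curation beyond the chromosome-boundary
  rule is applied.
- Probability outputs are not calibrated; only the argmax path is validated.
- The exact published region boundaries are not recoverable: they depend on
  the original cohort and an unstated segmentation parameterisation, so this
  package derives regions from whatever labelled cohort it is given.
- The generator's noise is homoscedastic Gaussian; heavy-tailed options are
  out of scope.
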