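---
title: "Demonstrating subject-identity leakage in slice-level fMRI hold-outs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demonstrating subject-identity leakage in slice-level fMRI hold-outs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sliceleak)
```

## The problem

Deep-learning studies of brain disease frequently train 2D convolutional
networks on individual slices cut from 3D or 4D neuroimaging volumes. Each
subject then contributes hundreds to thousands of slices, and how those
slices are divided into training and test sets decides whether the reported
performance means anything. Two strategies are in circulation:

* **subject-level hold-out** ("brain hold-out"): every slice of a subject
  goes wholly to train or wholly to test. The test set consists of brains
  the model has never seen — the situation a diagnostic tool faces in
  clinical use.
* **slice-level hold-out**: slices are pooled and split, say 70/30, with no
  regard for which subject they came from. Almost every subject then has
  slices on both sides of the split.

The second strategy leaks subject identity. Brain anatomy is a biometric
fingerprint: two slices of the same brain are far more alike than two
slices of different brains with the same diagnosis. A classifier evaluated
under slice-level hold-out can therefore score highly by *recognizing the
patient*, not the disease — and the inflation can be dramatic (published
replication work on Alzheimer's classification from resting-state fMRI
found subject-level medians near chance, around 46% accuracy, against
slice-level medians above 84% on the same data and model).

`sliceleak` packages that comparison as a controlled, fully synthetic
experiment in which the two signals — subject identity and diagnosis — are
generated with known amplitudes, so the leakage mechanism can be isolated,
measured and regression-tested.

## The generative model

Each subject's 4D BOLD volume (H × W × D spatial voxels × T timepoints) is

```
data[x, y, z, t] = baseline
                 + fingerprint_sd * F_subject[x, y, z]
                 + class_effect_sd * G_class[x, y, z]
                 + noise[x, y, z, t],     noise ~ N(0, noise_sd²) i.i.d.
```

`F_subject` is a smooth Gaussian random field drawn once per subject and
constant over time — the anatomical identity signal. `G_class` is a smooth
field shared by all subjects with the same diagnosis — the genuine
diagnostic signal. Both fields are standardized (mean 0, sd 1), so the two
`*_sd` parameters are amplitudes in the same units as the noise sd.
Smoothness matters: the fields are low-pass filtered white noise (Gaussian
kernel, sd `smoothness` voxels), giving them the spatial coherence that a
convolutional network can exploit, as it exploits real anatomy. Per-subject
and per-class sub-seeds are hashed from the master seed, so a cohort is
reproducible and order-independent.

What the generator deliberately does *not* emulate: hemodynamics, motion,
scanner drift, registration error, or any physiology. Passing the leakage
demonstration here shows that the *evaluation design* is broken, not that
any particular real dataset has a particular effect size. Conversely the
fingerprint-driven inflation observed here is a lower bound on mischief:
real anatomy is an even stronger identity signal than a smooth random
field.

## The pipeline

`run_experiment()` chains the steps a slice-based study performs:

1. **Cohort**: `n_per_class` subjects per diagnosis; for subjects with
   several scan dates only the earliest scan is kept
   (`select_earliest_scan()`), avoiding duplicate anatomy.
2. **Slicing**: each volume is cut along depth and time into D × T
   axial slices (a full-scale (99, 117, 95, 197) volume yields 18,715; the
   (…, 976) variant 92,720).
3. **Filtering**: per subject, only slices whose mean BOLD signal reaches
   the 90th percentile are kept — the top ~10%, slices with prominent
   signal. The percentile uses linear interpolation between order
   statistics (`quantile` type 7) with ties at the threshold retained, so
   on 18,715 distinct means exactly 1,872 slices survive, matching the
   "around 1,871" of the full-scale design; the exact count at a tie or a
   different interpolation convention would differ by at most one, which is
   why the harness documents the convention rather than guessing another.
4. **Sampling**: a fixed number of slices per subject (700 at full scale)
   drawn uniformly without replacement, seeded per subject.
5. **Splitting**: `split_by_subject()` (17/8 at full scale, giving exactly
   11,900 train and 5,600 test slices per diagnosis at 25 × 700) or
   `split_by_slice()` (70/30, floor for the train count). Both are
   stratified per class; `audit_leakage()` flags any plan in which a
   subject appears on both sides.
6. **Preparation**: per-slice min–max normalization to [0, 1], bilinear
   resize, channel triplication. The enhancement recipe is a documented
   stand-in — per-slice normalization is chosen precisely because it
   cannot carry statistics across the split boundary.
7. **Training and evaluation**: a binary CNN per problem and mode;
   accuracy, sensitivity and specificity in percent; medians across
   problems; slice-minus-subject gaps per metric.

## The classifier

Two architectures share one seeded CNN engine (written in R, with im2col
convolution, batch normalization, max/average pooling, residual blocks,
dropout and Adam, all verified against finite-difference gradients):

* `resnet18` — the standard 18-weight-layer residual network with its
  final dense layer remodeled into a binary head (linear → ReLU →
  dropout 0.2 → linear to 2 logits) and all layers trainable. This is the
  full-scale architecture; training it is GPU-scale work and no test
  requires it.
* `tinycnn` — three conv–ReLU–avgpool blocks (8, 16, 32 filters) with the
  identical head, for CPU desk-scale runs. All quantitative properties of
  the harness are established on it.

Choices the full-scale description leaves open are fixed as: Adam
optimizer, cross-entropy loss over the 2 logits, 5 default epochs, no
early stopping, single-run metrics (no multi-seed averaging inside a run).
Pretrained weights are optional and never downloaded; the random-init path
is fully supported and is what every test uses.

## Desk-scale study conditions

The shipped `default_config()` freezes the desk-scale conditions:

| parameter | value | why |
|---|---|---|
| classes, subjects | CN vs. AD, 10 per class | smallest cohort with a comfortable 7/3 subject split |
| volume shape | (24, 28, 22, 20) | desk-scale spatial grid; T = 20 so the 90th-percentile filter leaves 44 slices, enough to sample 40 |
| fingerprint_sd | 3 | identity signal well above noise, as real anatomy is |
| class_effect_sd | 0 | *no diagnostic signal at all* — any above-chance test accuracy is leakage |
| noise_sd | 1 | unit reference scale |
| slices per subject | 40 | after the 90th-percentile filter on 440 slices |
| split | 7/3 subjects vs. 70/30 slices | scaled-down analogue of 17/8 |
| model | tinycnn, 32 px, 3 epochs, batch 32, lr 1e-3 | enough optimization steps (~54) to memorize fingerprints under slice hold-out on a CPU in ~30 s |

The signal amplitudes are free parameters of the synthetic design — the
full-scale data they emulate carries no published signal/noise
characterization — and were calibrated once so that the leaky split can
actually exploit the fingerprint within three epochs; they are not
estimates of any real quantity. With these conditions, slice-level hold-out
reaches high accuracy while subject-level hold-out stays at chance, a gap
far above the 15-point margin the test suite asserts.

### What "chance" means under subject hold-out

A trained network scores all slices of an unseen subject nearly
identically, because the subject's fingerprint dominates every slice. The
independent statistical unit of subject-level test accuracy is therefore
the *subject*, not the slice: with 6 test subjects per run the accuracy is
approximately a Binomial(6, ½) fraction, not a Binomial(240, ½) one. The
package's chance-level checks accordingly pool test subjects across seeds
and use the binomial interval at the subject count. Using the slice count
would shrink the interval by a factor of ~6 and reject a perfectly null
model most of the time.

## Numerical conventions and degenerate cases

* Percentile filtering: `mean_signal >=` the type-7 interpolated
  percentile; ties retained; original slice order preserved.
* Slice sampling: without replacement; a stack smaller than the request is
  an error unless replacement is explicitly allowed (then logged).
* Slice split: `floor(train_fraction * N)` to train, remainder to test —
  deterministic and side-stable.
* Prediction ties (score exactly 0.5) break toward class 0.
* Degenerate confusion denominators (no positives or no negatives in a
  test set) yield `NA` with an `undefined_*` flag, never a fabricated 0 or
  100.
* Metrics are kept at full precision internally; rounding to two decimals
  happens only in the Markdown report.
* Batch size auto-clamps to the dataset size with a warning.
* The positive class of a problem "A vs. B" is B, configurable.

## Problem sizes used by the shipped tests

Unit tests run on volumes of at most (10, 10, 6, 4) voxels and training
sets of at most a few hundred 16 px images; the full leakage demonstration
uses the desk-scale conditions above (three runs of ~30 s each). The
full-scale shapes appear only as count arithmetic, never as materialized
arrays.

## Limitations

* The fingerprint is stationary across scans and time; real identity
  signals drift with session, motion and physiology. This makes leakage
  *cleaner* to demonstrate here, and means absolute accuracies do not
  transfer to real data.
* Slice-level metrics are reported per slice, not aggregated per subject;
  per-subject majority voting is a possible extension, not implemented.
* No significance testing beyond the descriptive gap; with synthetic
  replication over seeds, effect sizes are the honest currency.
* k-fold and site-aware cross-validation are out of scope; the package
  contrasts exactly the two hold-out strategies.
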