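---
title: "Methods: patch-based tumor classification for hyperspectral H&E microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based tumor classification for hyperspectral H&E microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hsipath)
```

## The problem

Histopathological diagnosis of glioblastoma (GB) on hematoxylin-and-eosin
(H&E) slides rests on morphological judgment: tumor regions are
hypercellular, with pleomorphic nuclei, while non-tumor brain tissue shows
sparse, regular nuclei. A hyperspectral (HS) microscope replaces each RGB
pixel with a full transmittance spectrum — here 826 bands over 400–1000 nm
from a push-broom line-scan camera (800 scan lines x 1004 sensor samples
per cube) — so a classifier can exploit spectral and spatial structure
together. `hsipath` implements the full analysis chain for such data:
radiometric normalization, spectral compression, patch extraction,
patient-disjoint cross-validation, a convolutional patch classifier,
per-patient evaluation, and sliding-window heat maps. Because clinical HS
cubes of this kind are not publicly available, the package also ships a
synthetic slide generator with the statistical structure the classifier
assumes, so that every stage is testable end to end.

## Processing model

**Flat-field correction.** A blank-area reference cube is averaged over its
scan lines, giving one reference spectrum per sensor sample — the
per-sample fixed-pattern response of a push-broom sensor. Specimen radiance
divided by this profile is normalized transmittance, clamped to [0, 1]
(values above 1 arise only from noise). The operation is exact under common
rescaling of cube and reference, and on noiseless synthetic slides it
recovers the generator's scene transmittance to machine precision — the
pipeline-consistency oracle the tests rely on.

**Band reduction.** Adjacent bands are highly correlated, so consecutive
non-overlapping groups of `group_size = 3` bands are averaged: 826 bands
become 275, and i.i.d. band noise variance drops by the group factor. Since
826 = 3·275 + 1, one band remains; the default `drop_last` policy discards
it (a `fold_into_last` alternative averages it into the final group). Any
grouping that yields 275 outputs is consistent with the instrument
configuration; the choice is recorded in the `band_plan` object.

**RGB synthesis.** The RGB baseline images and the patch-rejection rule
both need a colour rendering. Each channel is the inner product of the
pixel spectrum with a colour-matching weight curve (the CIE 1931 observer,
tabulated on the cube's wavelength grid from the Wyman–Sloan–Shirley
multi-lobe Gaussian fits), normalized so a unit spectrum maps to white.
Synthesis happens directly from whichever transmittance cube is at hand
(full or band-reduced); the two give visually identical renderings because
the weights are smooth.

**Patch extraction.** Cubes carry weak, per-cube labels, so classification
is patch-based: 87 x 87-pixel tiles on a top-left-anchored non-overlapping
grid (an 800 x 1004 cube yields a 9 x 11 grid, 99 tiles; residual margins
are discarded). Tiles dominated by blank light carry no tissue evidence and
are rejected: the tile's RGB rendering is converted to HSV, the hue channel
is binarized, and a tile whose light fraction exceeds 50% is discarded
(exactly 50% is retained — "more than half" rejects). Hue is undefined for
achromatic pixels, and blank light renders white, so the binarization
carries a saturation floor (`sat_floor = 0.05`): a pixel is light when its
hue falls below the threshold *or* its saturation is at the floor. The
default hue threshold 0.35 is the midpoint between the blank-light hue mode
(0) and the nearest tissue hue mode on default synthetic slides (nuclei
≈ 0.69, stroma ≈ 0.88); both parameters are plain fields of
`rejection_rule()`.

**Patient-disjoint folds.** All cross-validation is at the patient level:
within a fold the train, validation and test patient sets are disjoint;
across folds every patient is tested exactly once; each fold has exactly
one validation patient, who must carry both classes; every test set
contains at least one both-class patient. For the canonical 13-patient
cohort (5 tumor-only) and 4 folds this forces three test sets of 3 and one
of 4. Assignment is random under a seed except where constraints bind; a
`size_aware` policy variant sends the smallest single-class patients to the
largest test set, mirroring a manual adjustment sometimes applied to the
unbalanced fold. `assert_fold_plan()` re-checks any plan against the full
constraint set and is itself exercised over a thousand seeds in the tests.

**Class balancing.** Tumor patches are the minority (real campaigns collect
roughly twice as many non-tumor cubes), so the training set is balanced by
adding one spatially rotated copy of each minority patch. The rotation
angle is a right angle (default 180°, configurable to 90°/270°): lossless
permutations that leave per-band means exactly unchanged and need no
interpolation. The minority class is detected from the data rather than
hard-coded, and balancing is applied to the post-rejection training set.

## The classifier

The patch classifier is eight unpadded 3 x 3 convolutions (ReLU, 10%
dropout after every convolution), global average pooling, a dense ReLU
layer with dropout, a 2-unit logits layer and a softmax. Full-scale widths
are 256, 256, 512, 512, 1024, 1024, 1024, 1024 with a 256-unit dense
layer. Each unpadded convolution shrinks the spatial side by 2, so an
87-pixel patch reaches the pool at 71 x 71 — note that a published shape
table for this architecture lists the pool input as 73 x 73 with a 25 x 25
pool kernel, which is arithmetically inconsistent with eight unpadded
convolutions; this implementation performs true global averaging over
whatever spatial extent remains and reports layer shapes from the
consistent recurrence (successive conv inputs 87, 85, …, 73). The RGB and
HSI variants differ only in input channels (3 vs 275), keeping the
comparison architecture-controlled.

`scale` multiplies all channel widths, preserving depth and spatial
arithmetic: `scale = 1` is the full design, and `scale = 0.0625` (widths
16, 16, 32, 32, 64, 64, 64, 64; dense 16) is the desk-scale default used
for synthetic experiments on one CPU.

**Input normalization.** Each patch is standardized per band by its own
mean and standard deviation before entering the network (the default,
`normalization = "patch"`). This cancels slide- and patient-level staining
intensity — which otherwise offers the network an easy shortcut that fails
on held-out patients, since staining intensity varies per patient but
carries no class information — and leaves the spatial and compositional
structure (the fraction and arrangement of nucleus-like pixels) that does
generalize. A `"global"` mode standardizing with training-set per-band
statistics is available and is exercised in the unit tests, where the
fixtures have no patient effects.

**Training.** Optimization is stochastic gradient descent at learning rate
1e-3 — in its classical per-sample form (`batch_size = 1`) with momentum
0.9. The choice matters at desk scale: training sets of one or two hundred
patches supply few gradient updates per epoch, and update count, not
gradient quality, limits convergence. Convolutional and dense weights are
He-initialized from the training seed; training starts the logits layer at
small random values so gradients reach every layer from the first step,
while a freshly built (untrained) model keeps exactly zero logits and is
therefore maximally uncertain. After each epoch the validation AUC is
recorded and the returned model carries the weights of the earliest
best-validation-AUC epoch. Epoch count and batch size are unstated in the
original design; the package records its defaults (10 epochs, batch 1)
inside every `train_config`. Forward and backward passes are im2col
gathers feeding BLAS matrix products, verified in the tests against a
direct triple-loop convolution and against numerical gradients.

## Evaluation

Tumor is the positive class. Sensitivity TP/(TP+FN), specificity
TN/(TN+FP) and accuracy (TP+TN)/total are computed from a thresholded
confusion matrix (threshold 0.5, ties predicted positive; the threshold is
a recorded parameter, not a constant). AUC is the Mann–Whitney probability
that a random tumor patch outscores a random non-tumor patch, ties counted
half — implemented with midranks and tested to 1e-12 against the exhaustive
pairwise count and against an independent ROC package. Zero denominators
yield `NA`, never an error: a tumor-only patient has no defined specificity
or AUC. Per-patient rows aggregate by the unweighted mean and sample
standard deviation over non-`NA` values; values aggregate unrounded, and
display rounding (percentages to integers, AUC to two decimals, halves away
from zero) is applied last. Quality-control exclusions — cubes flagged for
ink contamination, defocus, processing artifacts, blood or necrosis — are
manifest metadata applied only at evaluation time: flagged cubes drop out
of the test set and the classifier is not retrained.

**Heat maps.** For qualitative review, whole cubes are scored with an
87-pixel window slid at 23-pixel stride (a full-size cube gives a 32 x 40
probability grid). Each pixel's overlay value is the unweighted mean of all
windows covering it — an order-independent convex combination that stays in
[0, 1]. Margins never covered by a full window borrow the nearest covered
pixel's value for rendering only; the probability grid itself contains no
extrapolated cells. No blank-light rejection is applied at inference:
specimen-free windows simply score low.

## The synthetic data generator

`generate_slide()` emulates the features the classifier depends on, and
only those:

- **Stain optics.** Beer–Lambert transmittance with two Gaussian absorbance
  bands per stain: hematoxylin-like (peak 590 nm, secondary 445 nm) and
  eosin-like (peak 525 nm, secondary 490 nm). Nuclei are
  hematoxylin-dominant, stroma eosin-dominant. The peaks are chosen to make
  the two spectra visibly distinct below 700 nm and flat/bright in the
  700–1000 nm tail — tunable configuration emulating the qualitative shape
  of measured tissue spectra, not asserted stain chemistry.
- **Morphology.** Nuclei are filled ellipses from a seeded Poisson point
  process with radius jitter; tumor scenes default to 20 nuclei per
  100 x 100 px versus 8 for non-tumor, with larger radius variance (2.5 vs
  1.2 px around a 6 px mean) as a pleomorphism proxy. Cell density is the
  class-discriminating spatial property, matching how such classifiers are
  understood to work on real GB slides.
- **Illumination and noise.** A smooth halogen-like ramp rising toward the
  near-infrared, jittered ±10% per slide (shared between a cube and its
  blank reference, which is what flat-fielding must undo); additive white
  Gaussian noise (default sd 5 radiance counts against a ~1000-count
  illumination peak), clipped at zero.
- **Blank light.** A right-edge strip of pure illumination occupying
  `blank_fraction` (default 15%) of the columns, giving the rejection rule
  real work and the heat maps a known cell-free region.
- **Cohorts.** `generate_cohort()` draws one log-normal (sd 0.2) stain
  factor pair per patient — making between-patient spectral variance exceed
  within-patient variance, the property that forces patient-disjoint
  validation — and writes ENVI cube/reference pairs, plain-text mask
  bitmaps and a manifest. The last `tumor_only_patients` patients carry
  tumor ROIs only; non-tumor ROIs contribute twice the cubes of tumor ROIs,
  mirroring the ~2:1 class imbalance of real campaigns. All randomness
  descends from one integer seed through a counter-based splitting scheme,
  so any slide regenerates independently and cohort generation is
  bit-reproducible.

What the generator deliberately does *not* model: chromatic texture inside
nuclei, scattering and defocus optics, stain colocalization chemistry,
spatial illumination gradients, or annotation noise. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that the
classifier can exploit density-plus-spectrum structure; they do not
demonstrate clinical performance, which requires real slides.

## Problem sizes and numerical choices

Unit tests run the classifier on 17-pixel patches (the smallest side eight
unpadded convolutions permit) with raised nuclear densities so a tiny patch
still spans several nuclei. The end-to-end experiment uses a 10-patient
cohort (4 tumor-only) of 261 x 348 x 24-band cubes — each cube tiles into a
3 x 4 grid of 87-pixel patches, of which the blank strip typically removes
three — trained at `scale = 0.0625` for 6 epochs, with a 3-epoch
label-shuffled null control; these sizes were chosen so the whole
experiment is comfortable on a single CPU while leaving the learning
problem non-trivial (held-out patients, patient-level stain shifts). The
held-out score is the unweighted mean of per-patient AUCs over the fold's
test patients, mirroring how the clinical tables aggregate: AUC is a
within-patient ranking quantity here, and pooling scores across patients
would mix in between-patient probability offsets that no per-patient
table measures. The label-shuffled null is the opposite case: per-patient
AUC of a smooth no-signal model is unstable at a handful of test patients
(any random direction in feature space correlates with composition within
a patient), while the pooled patch-level AUC is exactly the statistic that
leakage would inflate — so the null control is asserted on the pooled
AUC.
Degenerate inputs are handled explicitly: empty tile grids for undersized
images, `NA` metrics for single-class patients, warnings (not errors) for
slides that are all blank light, and hard errors for contradictory headers,
leaking folds, unlabeled cubes and band mismatches.

Two open choices were resolved as follows. The published 826→275 reduction
does not say how the residual band was treated; `drop_last` was chosen as
the simplest rule and is recorded in the plan object. Whether RGB synthesis
precedes or follows band reduction is likewise unstated; this package
synthesizes RGB from whichever transmittance cube it is given, and the
patch-rejection rule uses the rendering of the same cube it tiles, keeping
decisions local and order-independent. The rotation used for augmentation
is unstated beyond being "a single spatial rotation"; 180° is the default
because it is valid for any rectangular patch and interpolation-free.

## Known limitations

The classifier is a faithful desk-scale implementation, not a re-creation
of trained clinical weights; published per-patient clinical numbers are
used only as worked examples for the aggregation arithmetic. Training is
single-threaded R on BLAS and is practical up to a few hundred desk-scale
patches; full-scale (width 1) training on 275-band patches would require a
GPU framework outside this package's scope. The hue threshold is calibrated
on the synthetic stain model; real slides need it re-estimated (the rule
object makes it explicit). The ENVI reader handles the BIL/BIP/BSQ
float32/float64 subset this pipeline writes, not every vendor dialect.
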