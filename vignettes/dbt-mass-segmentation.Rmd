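---
title: "Patch-based U-Net segmentation of DBT breast masses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based U-Net segmentation of DBT breast masses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Digital breast tomosynthesis (DBT) reconstructs a stack of thin slices
(typically 50-80 at 1 mm spacing) from limited-angle mammographic
projections. Masses in these slices are low-contrast, embedded in textured
fibroglandular tissue, and corrupted by Poisson photon noise from the
deliberately low dose. `dbtseg` implements a complete pixel-wise
segmentation pipeline for such stacks: morphological enhancement, balanced
patch training of a valid-convolution U-Net under an F-beta overlap loss,
patch-vote fusion, and size-filter postprocessing — plus a synthetic
phantom generator, so the whole pipeline is testable end to end without
clinical data (which, for the sites this design models, is not publicly
available).

## Pipeline stages and their models

### Enhancement

Each slice is enhanced with the composite top-hat residue

I_tophat = I − min(open(close(I, s_c), s_o), I),

where `s_c` (closing) and `s_o` (opening) are disc structuring elements.
Closing with a small disc fills dark texture gaps; the subsequent opening
with a disc *larger than a mass* removes mass-scale structures from the
background estimate, so the residue retains candidate masses and suppresses
larger-scale anatomy. The result is multiplied by a constraint field: the
pointwise maximum of isotropic Gaussians (peak 1, sigma = 5 mm) centred on
candidate locations obtained by greedy exclusion — draw a mark at random,
keep it, discard all marks within 5 mm, repeat. Disc radii have no single
canonical value; the defaults (r_close = 15 px, r_open = 40 px at clinical
resolution; 4/14 px at the phantom's 0.5 mm/px) are chosen so the opening
disc exceeds the largest expected mass radius. Where no external
marks exist, marks default to bright local maxima of the enhanced slice
(99th percentile), since the provenance of marks is otherwise unspecified.
Both choices are exposed in the configuration. The grayscale morphology is
delegated to EBImage and computed in [0, 1] normalized space (min/max
filters commute with positive rescaling; EBImage's grayscale erosion
assumes that range).

### Patches and balancing

Patches are taken on a regular per-slice grid (axial plane). A patch is
labelled *mass* when its mask fraction reaches 0.05 — a small positive
threshold so a single boundary pixel does not make a positive. Because the
mass class is rare, each epoch draws the *same number* of patches per class
(without replacement when the pool allows; the per-class count defaults to
the minority-pool size). Augmentation is restricted to rotations by
multiples of 90 degrees: translations would produce different patches with
possibly different labels, and the right-angle subgroup is exact on the
pixel lattice.

One subtlety of valid (unpadded) convolutions: the network only predicts —
and is only supervised on — the *centre window* of each patch (e.g. the
central 36 px of a 76 px patch at depth 3). Training therefore extracts
patches from mirror-padded slices with stride equal to the output-window
size, so the supervised windows tile every pixel, exactly mirroring how
prediction tiles a test slice. For the same reason the balancing pools are
built from the *supervised window* content rather than the whole-patch
label: a patch whose mass lies entirely in the cropped margin trains as
background.

### Network

The U-Net is the canonical contracting/expansive design: two 3x3 valid
convolutions + ReLU per level, 2x2 max pooling (stride 2), channel count
doubling per level down and halving per level up, 2x2 up-convolutions,
skip concatenation of centre-cropped contracting features, and a final 1x1
convolution onto 2 classes with a softmax head. At the default depth 5 /
base 64 this is exactly 23 convolutional layers (18 3x3, 4 up-convolutions,
1 1x1); a 572 px input maps to a 388 px output. The implementation is a
from-scratch RcppArmadillo engine (im2col + BLAS matrix multiply, exact
analytic backward pass); the test suite checks the analytic gradients of
the full network against finite differences.

### Loss and optimizer

Training minimizes `1 − F_beta(S, T)` with

F_beta = (1 + beta^2) * sum(s_i t_i) / (sum(s_i) + sum(t_i)),

applied to the predicted mass-class probability map (beta = 1 by default,
where the measure coincides with the Dice coefficient on binary inputs).
This overlap loss is the appropriate objective under extreme pixel
imbalance — a constant background prediction scores zero overlap rather
than high accuracy. Conventions: F(0, 0) = 1 (a correct empty prediction
is rewarded; the raw ratio is 0/0 there), and since F_beta is a similarity
the loss is its complement 1 - F_beta. The optimizer is Adam at learning rate
2e-4, at most 150 epochs, batch size 1 (large tiles over large batches;
Adam's first-moment decay of 0.9 supplies the heavy momentum that makes
single-sample updates coherent), Xavier-normal kernel initialization, zero
biases.

Two numerical notes from this implementation. First, inputs are z-scored
by the training-set mean and standard deviation (stored in the model and
reapplied at prediction); with raw photon-count scales the optimization is
markedly less stable. Second, `fbeta_loss` exposes an optional smoothing
constant (numerator and denominator) because the exact ratio has an
identically zero gradient on empty-target patches; the default is 0 (the
exact formula) after the smoothed variant proved counter-productive under
Adam — the smoothing term's tiny but perfectly *consistent* suppression
gradient is amplified by Adam's per-weight normalization until it dominates
the noisy mass-patch signal. With the exact loss, false-positive control
comes from the background pixels of mass-containing patches, which is
sufficient in practice.

### Fusion

For image-level labels, each test slice's patch predictions p_i are fused
by one of four schemes: majority voting over hard labels; maximum
probability; sum of probabilities; and connectivity voting, which weights
the class vote v_k by the number c_k of 8-adjacent (including diagonal)
patch pairs sharing hard label k. Conventions: c_k counts *ordered* pairs
(any consistent convention leaves the argmax unchanged — the suite verifies
the normalization by sum(c_k') cancels); ties break to the lowest class
index; when every c_k is zero the scheme falls back to majority voting.
The per-pixel heatmap and the image-level vote are parallel outputs — the
pipeline does not mix them.

### Postprocessing

The heatmap is thresholded at 0.5 (>= rule, exposed for ROC sweeps),
connected components smaller than 50 voxels (strict `< 50`,
26-connectivity in 3D, both exposed) are removed as false positives, and a
per-slice 3x3 binary median filter smooths the mass boundaries. The
50-voxel rule is applied per volume — the literal reading of a volumetric
criterion.

### Evaluation

Sen = TP/(TP+FN), Spe = TN/(TN+FP), Acc = (TP+TN)/total are computed
voxel-wise; zero-denominator metrics are reported as missing, never
silently 0 or 1. ROC/AUC sweeps the binarization threshold over the
heatmap's unique scores *before* postprocessing (cluster filtering would
destroy the score ordering); with the full threshold set the trapezoidal
AUC equals the rank-statistic (Mann-Whitney) AUC exactly, which the suite
asserts to 1e-9. The cross-site runner evaluates the six train/test
combinations (same-site x2, cross-site x2, pooled x2) under 5-fold
cross-validation. Folds partition *volumes*, not slices or patches:
slice-level splitting would leak near-identical neighbouring slices of the
same lesion between training and test.

## The phantom: what it emulates, what it does not

`generate_phantom` produces Poisson photon-count stacks over a smooth
Gaussian-correlated background texture (unit mean, 15% amplitude) with
ellipsoidal lesions of elevated intensity and Gaussian-feathered edges,
plus exact masks and the per-slice 2D bounding boxes that mimic weak
radiologist annotation. Defaults and rationale:

* in-plane semi-axes 4-8 mm — screening-detected masses are typically
  8-16 mm in diameter; the through-plane semi-axis is capped by the stack
  depth, so lesions in thin test stacks are oblate;
* two site profiles for cross-site experiments — H1 (contrast 0.40,
  texture correlation 8 px, 400 photons) and H2 (contrast 0.55, coarser
  texture 12 px, 250 photons) — differing in contrast, texture and dose so
  that cross-site transfer is genuinely non-trivial;
* test-scale geometry (12 slices, 96-128 px, 0.5 mm/px) far below the
  clinical 50-80 slices at ~0.1 mm/px, so the full pipeline runs in CPU
  minutes.

The phantom deliberately omits acquisition physics (no projection geometry,
no reconstruction artifacts, no anatomical structures beyond texture), so a
passing pipeline demonstrates the *machinery* — losses, tiling, fusion,
metrics — not clinical-grade segmentation. Clinical DBT archives of the
kind this design models are private, so phantom numbers are structurally
analogous to clinical results, never comparable with them.

## Problem sizes used by the tests and the acceptance script

The reduced study conditions are: smoke training — one 12-slice 96 px H1
phantom with 2 lesions, 76 px patches (36 px supervised windows), U-Net
depth 3 with 8 base channels, 30 epochs; cross-site study — five 8-slice
48 px volumes per site with one 3-6 mm lesion each, depth-2/4-channel
network, 28 px patches, 4 epochs per fold, 6 combinations x 5 folds. On
these conditions the smoke training reaches a pooled patch F1 around 0.9
and volume-level accuracy above 0.99, and the cross-site study reproduces
the qualitative ordering expected of the full-scale experiment (same-site
>= cross-site; pooled training recovers most of the gap) — a stochastic
tendency that is logged, not asserted.

## Known limitations

* No GPU and no 3D convolutions; the engine is CPU-bound and sized for
  phantom-scale problems, not clinical volumes.
* Dropout, transfer learning, and non-rotational augmentation are out of
  scope by design.
* The image-level voting schemes are reported per slice; how image labels
  interact with the per-pixel map is left open deliberately.
* The patch labelling threshold, patch size, and number of training
  patches have no canonical values in this problem domain; all are
  configuration parameters with documented defaults.
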